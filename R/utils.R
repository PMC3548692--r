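# Internal helpers: conditions, coordinate conventions, TSV I/O, sub-seeding.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_usage <- function(...) {
  stop(structure(class = c("snpprio_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_integrity <- function(...) {
  stop(structure(class = c("snpprio_integrity_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# 1-based inclusive -> internal 0-based half-open, and back.
to_internal_coords <- function(start, end, convention = "0based-halfopen") {
  convention <- match.arg(convention, c("0based-halfopen", "1based-inclusive"))
  if (convention == "1based-inclusive") start <- start - 1L
  list(start = as.integer(start), end = as.integer(end))
}

from_internal_coords <- function(start, end, convention = "1based-inclusive") {
  convention <- match.arg(convention, c("0based-halfopen", "1based-inclusive"))
  if (convention == "1based-inclusive") start <- start + 1L
  list(start = as.integer(start), end = as.integer(end))
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

trimws_split <- function(tokens, sep = ",") {
  out <- trimws(strsplit(tokens, sep, fixed = TRUE)[[1]])
  out[nzchar(out)]
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Stochastic drivers (LOOCV cells, per-seed simulations) derive independent
#' RNG seeds deterministically from one master seed, so that every run is
#' reproducible from a single integer. The result always lies in
#' `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the consumer.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  label <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}
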