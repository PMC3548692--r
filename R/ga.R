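# Weight learning: genetic algorithm against disease benchmarks.
# Fitness = 1 - mean sensitivity (lower is better), evaluated after filtering
# scores at the relative threshold T_eps = epsilon * max(sigma) and penalized
# (sentinel 2.0) whenever the retained fraction |Y|/|S| reaches Tr for any
# training disease. Leave-one-out cross-validation over the (epsilon, Tr)
# grid reports per-cell mean sensitivity / specificity / accuracy.

#' Construct a disease benchmark
#'
#' A benchmark is a disease's gene set, its candidate SNP universe `S` (all
#' SNPs of its genes within the flanking region) and its certified SNP set
#' `A`. Certified SNPs outside `S` are dropped with a counted warning
#' (attribute `n_dropped_certified`), so `A` is always a subset of `S`.
#'
#' @param disease_id label.
#' @param genes character vector of gene ids.
#' @param S candidate SNP rsids.
#' @param A certified SNP rsids.
#' @return a `disease_benchmark` list.
#' @export
disease_benchmark <- function(disease_id, genes, S, A) {
  if (length(S) == 0) stop_integrity("benchmark ", disease_id, ": S is empty")
  dropped <- setdiff(A, S)
  if (length(dropped) > 0)
    warning("benchmark ", disease_id, ": ", length(dropped),
            " certified SNP(s) outside S dropped", call. = FALSE)
  A <- intersect(A, S)
  structure(list(disease_id = disease_id, genes = unique(genes),
                 S = unique(S), A = A,
                 n_dropped_certified = length(dropped)),
            class = "disease_benchmark")
}

#' Load disease benchmark files
#'
#' Each benchmark file is a one-row TSV with columns `disease_id`, `genes`
#' and `certified` (comma-separated lists). The candidate universe `S` is
#' rebuilt from the annotation store: every SNP mapped to one of the
#' disease's genes within the flanking region.
#'
#' @param paths benchmark file paths (or a directory containing them).
#' @param gene_snp_map a `gene_snp_map` from [map_snps_to_genes()].
#' @return list of `disease_benchmark` objects.
#' @export
load_benchmarks <- function(paths, gene_snp_map) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.tsv$", full.names = TRUE)
  if (length(paths) == 0) stop_usage("no benchmark files found")
  lapply(sort(paths), function(p) {
    row <- read_tsv(p)
    if (nrow(row) != 1 ||
        !all(c("disease_id", "genes", "certified") %in% names(row)))
      stop_usage("malformed benchmark file: ", p)
    genes <- trimws_split(row$genes)
    S <- sort(unique(gene_snp_map$rsid[gene_snp_map$gene_id %in% genes]))
    disease_benchmark(row$disease_id, genes, S, trimws_split(row$certified))
  })
}

#' Relative score threshold
#'
#' `T_eps = epsilon * sigma_max`, a fraction of the reference maximum score.
#' The reference defaults to the best observed score over `S`; the optimizer
#' passes the maximum attainable score `sum(w)` (every feature score at 1)
#' instead, which is equally invariant to rescaling the weight vector but
#' does not depend on the extreme order statistic of the sample. Either way
#' the threshold scales with the weights, never with an absolute constant.
#' All-zero scores give `T_eps = 0` with a degenerate-weights warning.
#'
#' @param sigmas numeric scores over a disease's candidate set S.
#' @param epsilon value in `(0, 1]`.
#' @param sigma_max reference maximum; default `max(sigmas)`.
#' @return the threshold.
#' @export
score_threshold <- function(sigmas, epsilon, sigma_max = NULL) {
  if (length(sigmas) == 0) stop_usage("S is empty")
  if (length(epsilon) != 1 || is.na(epsilon) || epsilon <= 0 || epsilon > 1)
    stop_usage("epsilon must lie in (0, 1]")
  m <- sigma_max %||% max(sigmas)
  if (m == 0) warning("all scores are zero (degenerate weights)", call. = FALSE)
  epsilon * m
}

#' High-scoring SNP set
#'
#' Strict comparison: `Y = { s_i : sigma_i > T_eps }`, so at `epsilon = 1`
#' the set is empty.
#'
#' @param sigmas named numeric scores (names are rsids).
#' @param t_epsilon threshold from [score_threshold()].
#' @return character vector of rsids in Y.
#' @export
high_scoring_set <- function(sigmas, t_epsilon) {
  names(sigmas)[sigmas > t_epsilon]
}

#' Confusion counts of a filtered set against a benchmark
#'
#' `P = |A intersect Y|` (true positives), `N = |A setminus Y|` (false
#' negatives), `FP = |Y setminus A|`, `TN` the rest of S. Sensitivity
#' `P/|A|`, specificity `TN/(TN+FP)`, accuracy `(P+TN)/|S|`.
#'
#' @param Y rsids of the high-scoring set.
#' @param benchmark a `disease_benchmark`.
#' @return list of counts and derived rates.
#' @export
confusion <- function(Y, benchmark) {
  S <- benchmark$S; A <- benchmark$A
  if (length(A) == 0)
    stop_usage("benchmark ", benchmark$disease_id,
               " has no certified SNPs: sensitivity undefined")
  Y <- intersect(Y, S)
  P <- length(intersect(A, Y))
  N <- length(A) - P
  FP <- length(setdiff(Y, A))
  TN <- length(S) - P - N - FP
  list(P = P, N = N, FP = FP, TN = TN,
       sensitivity = P / (P + N),
       specificity = if (TN + FP == 0) NA_real_ else TN / (TN + FP),
       accuracy = (P + TN) / length(S))
}

#' Prepare per-disease scoring data for the GA
#'
#' Precomputes, per benchmark, the normalized feature-score matrix restricted
#' to `S` and the certified indicator, so a fitness evaluation is one
#' matrix-vector product per disease.
#'
#' @param benchmarks list of `disease_benchmark`.
#' @param fnorm normalized feature score matrix (SNPs x features, rsid
#'   rownames), e.g. from [normalize_matrix()].
#' @return list of per-disease lists `(disease_id, F, certified, benchmark)`.
#' @export
prepare_ga_data <- function(benchmarks, fnorm) {
  lapply(benchmarks, function(b) {
    missing_snps <- setdiff(b$S, rownames(fnorm))
    if (length(missing_snps) > 0)
      stop_integrity("benchmark ", b$disease_id, ": ", length(missing_snps),
                     " SNP(s) missing from the feature matrix")
    F <- fnorm[b$S, , drop = FALSE]
    list(disease_id = b$disease_id, F = F,
         certified = rownames(F) %in% b$A, benchmark = b)
  })
}

#' GA fitness of a weight vector
#'
#' Per training disease: score, filter at the relative threshold
#' `T_eps = epsilon * sum(w)` (a fraction of the maximum attainable score),
#' measure sensitivity. If the retained fraction `|Y|/|S|` reaches `Tr` for
#' any training disease the sentinel penalty 2.0 is returned (strictly worse
#' than any feasible fitness in `[0,1]`); otherwise `1 - mean sensitivity`
#' (`aggregate = "mean"`) or `1 - pooled P / pooled |A|`
#' (`aggregate = "pooled"`).
#'
#' @param w weight vector (registry order).
#' @param data from [prepare_ga_data()].
#' @param epsilon relative threshold factor in `(0, 1]`.
#' @param Tr filtering-ratio bound.
#' @param aggregate `"mean"` or `"pooled"`.
#' @return fitness value (lower is better).
#' @export
ga_fitness <- function(w, data, epsilon, Tr, aggregate = c("mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  sens <- numeric(length(data))
  pooled_p <- 0; pooled_a <- 0
  t_eps <- epsilon * sum(w)
  for (i in seq_along(data)) {
    d <- data[[i]]
    sigma <- drop(d$F %*% w)
    y <- sigma > t_eps
    if (sum(y) / length(y) >= Tr) return(2.0)
    p <- sum(y & d$certified)
    sens[i] <- p / sum(d$certified)
    pooled_p <- pooled_p + p
    pooled_a <- pooled_a + sum(d$certified)
  }
  if (aggregate == "mean") 1 - mean(sens) else 1 - pooled_p / pooled_a
}

#' GA configuration
#'
#' Defaults follow the published schedule: 100 generations of 120
#' individuals; each generation keeps the 10 best unmodified, adds 10 fresh
#' random individuals and fills the remaining 100 slots with recombinants of
#' the best 50.
#'
#' @param generations,population,elite_pool,n_random,n_elite,n_recombinant
#'   GA schedule; `n_random + n_elite + n_recombinant` must equal
#'   `population`.
#' @param epsilon,Tr fitness parameters.
#' @param mut_prob,mut_sd per-coefficient mutation probability and Gaussian
#'   standard deviation.
#' @param seed RNG seed.
#' @param aggregate sensitivity aggregation across diseases.
#' @return a `ga_config` list.
#' @export
ga_config <- function(generations = 100, population = 120, elite_pool = 50,
                      n_random = 10, n_elite = 10, n_recombinant = 100,
                      epsilon = 0.3, Tr = 0.25, mut_prob = 0.05, mut_sd = 0.1,
                      seed = 1, aggregate = "mean") {
  if (n_random + n_elite + n_recombinant != population)
    stop_usage("n_random + n_elite + n_recombinant must equal population")
  if (elite_pool > population)
    stop_usage("elite_pool cannot exceed population")
  structure(list(generations = generations, population = population,
                 elite_pool = elite_pool, n_random = n_random,
                 n_elite = n_elite, n_recombinant = n_recombinant,
                 epsilon = epsilon, Tr = Tr, mut_prob = mut_prob,
                 mut_sd = mut_sd, seed = seed, aggregate = aggregate),
            class = "ga_config")
}

#' Scale the GA schedule down proportionally
#'
#' Keeps the random/elite/recombinant proportions of the default scheme at a
#' smaller population size, for reduced experiments.
#'
#' @param population target population size.
#' @param generations number of generations.
#' @param ... overrides passed to [ga_config()].
#' @return a `ga_config`.
#' @export
ga_config_scaled <- function(population = 40, generations = 30, ...) {
  f <- population / 120
  n_random <- max(1L, round(10 * f))
  n_elite <- max(1L, round(10 * f))
  ga_config(generations = generations, population = population,
            elite_pool = max(2L, round(50 * f)), n_random = n_random,
            n_elite = n_elite,
            n_recombinant = population - n_random - n_elite, ...)
}

#' Random initial population
#'
#' Coefficients are i.i.d. uniform on `[0, 1]`; uses the current RNG state.
#'
#' @param n_features number of coefficients per individual.
#' @param size population size.
#' @return matrix `size x n_features`.
#' @export
init_population <- function(n_features, size) {
  if (size <= 0) stop_usage("population size must be positive")
  matrix(stats::runif(size * n_features), nrow = size, ncol = n_features)
}

#' Recombine two individuals
#'
#' Uniform crossover per coefficient, then per-coefficient mutation with
#' probability `mut_prob` adding a zero-mean Gaussian (`mut_sd`), clipped to
#' `[0, 1]`.
#'
#' @param p1,p2 parent coefficient vectors.
#' @param mut_prob,mut_sd mutation parameters.
#' @return child coefficient vector.
#' @export
recombine <- function(p1, p2, mut_prob = 0.05, mut_sd = 0.1) {
  if (length(p1) != length(p2)) stop_usage("parents have different lengths")
  take1 <- stats::runif(length(p1)) < 0.5
  child <- ifelse(take1, p1, p2)
  mut <- stats::runif(length(p1)) < mut_prob
  if (any(mut))
    child[mut] <- pmin(pmax(child[mut] + stats::rnorm(sum(mut), 0, mut_sd),
                            0), 1)
  child
}

#' Produce the next GA generation
#'
#' The `n_elite` lowest-fitness individuals are carried unmodified (ties
#' broken by index); `n_recombinant` children are bred from parent pairs
#' drawn uniformly (distinct within a pairing, with replacement across
#' pairings) from the `elite_pool` best; `n_random` fresh uniform individuals
#' complete the population.
#'
#' @param pop population matrix.
#' @param fitness evaluated fitness vector.
#' @param config a `ga_config`.
#' @return list with `pop` (new matrix) and `provenance`
#'   (`"elite"`, `"recombinant"`, `"random"` per row).
#' @export
next_generation <- function(pop, fitness, config) {
  if (nrow(pop) != config$population)
    stop_usage("population size mismatch")
  if (length(fitness) != nrow(pop))
    stop_usage("fitness vector misaligned with population")
  if (nrow(pop) < config$elite_pool)
    stop_usage("population smaller than elite pool")
  ord <- order(fitness, seq_along(fitness))   # deterministic index tie-break
  elite_idx <- ord[seq_len(config$n_elite)]
  pool_idx <- ord[seq_len(config$elite_pool)]
  n_feat <- ncol(pop)
  children <- matrix(0, config$n_recombinant, n_feat)
  for (k in seq_len(config$n_recombinant)) {
    pair <- sample(pool_idx, 2, replace = FALSE)
    children[k, ] <- recombine(pop[pair[1], ], pop[pair[2], ],
                               config$mut_prob, config$mut_sd)
  }
  randoms <- init_population(n_feat, config$n_random)
  new_pop <- rbind(pop[elite_idx, , drop = FALSE], children, randoms)
  provenance <- c(rep("elite", config$n_elite),
                  rep("recombinant", config$n_recombinant),
                  rep("random", config$n_random))
  list(pop = new_pop, provenance = provenance)
}

#' Run the genetic algorithm
#'
#' Seeds the RNG from `config$seed`, evolves `config$generations`
#' generations and returns the best-ever individual together with the
#' per-generation best-fitness trajectory (non-increasing by elitism).
#'
#' @param data from [prepare_ga_data()]; every benchmark must have a
#'   non-empty certified set.
#' @param config a `ga_config`.
#' @param fitness_fn fitness function `(w, data, epsilon, Tr, aggregate)`;
#'   defaults to [ga_fitness()]. Pluggable so the LOOCV driver can be
#'   exercised with a stub.
#' @return list with `best` (coefficients), `best_fitness`, `trajectory`,
#'   and `provenance` of the final generation.
#' @export
run_ga <- function(data, config = ga_config(), fitness_fn = ga_fitness) {
  for (d in data)
    if (sum(d$certified) == 0)
      stop_usage("benchmark ", d$disease_id, " has an empty certified set")
  n_feat <- ncol(data[[1]]$F)
  set.seed(config$seed)
  pop <- init_population(n_feat, config$population)
  provenance <- rep("random", config$population)
  best <- NULL; best_fit <- Inf
  trajectory <- numeric(config$generations)
  for (g in seq_len(config$generations)) {
    fitness <- apply(pop, 1, fitness_fn, data = data,
                     epsilon = config$epsilon, Tr = config$Tr,
                     aggregate = config$aggregate)
    i_best <- which.min(fitness)
    if (fitness[i_best] < best_fit) {
      best_fit <- fitness[i_best]
      best <- pop[i_best, ]
    }
    trajectory[g] <- best_fit
    if (g < config$generations) {
      nx <- next_generation(pop, fitness, config)
      pop <- nx$pop
      provenance <- nx$provenance
    }
  }
  list(best = best, best_fitness = best_fit, trajectory = trajectory,
       provenance = provenance)
}

#' Leave-one-out cross-validation over the (epsilon, Tr) grid
#'
#' For every grid cell and every held-out disease, trains on the remaining
#' diseases and evaluates sensitivity, specificity and accuracy on the
#' held-out one; each disease is validated exactly once per cell. Total runs
#' = diseases x |epsilon grid| x |Tr grid| (16 x 10 x 4 = 640 under the
#' default grids). Per-run sub-seeds derive deterministically from the master
#' seed, the held-out disease and the cell.
#'
#' @param data from [prepare_ga_data()] over all diseases.
#' @param epsilon_grid,tr_grid grids (defaults: 0.1..1.0 by 0.1 and
#'   0.25, 0.5, 0.75, 1.0).
#' @param config a `ga_config` template (its `epsilon`/`Tr` are overridden
#'   cell by cell).
#' @param train_fn trainer `(train_data, epsilon, Tr, seed) -> weights`;
#'   defaults to a [run_ga()] wrapper. A stub trainer exercises the driver
#'   without GA cost.
#' @return a `loocv_report`: list with `runs` (one row per run) and `cells`
#'   (per-cell means).
#' @export
loocv_grid <- function(data, epsilon_grid = seq(0.1, 1.0, by = 0.1),
                       tr_grid = c(0.25, 0.5, 0.75, 1.0),
                       config = ga_config(), train_fn = NULL) {
  if (length(data) < 2) stop_usage("LOOCV needs at least 2 diseases")
  if (is.null(train_fn))
    train_fn <- function(train_data, epsilon, Tr, seed) {
      cfg <- config
      cfg$epsilon <- epsilon; cfg$Tr <- Tr; cfg$seed <- seed
      run_ga(train_data, cfg)$best
    }
  runs <- vector("list", length(data) * length(epsilon_grid) * length(tr_grid))
  r <- 0L
  for (epsilon in epsilon_grid) for (Tr in tr_grid) {
    for (i in seq_along(data)) {
      held <- data[[i]]
      seed_i <- derive_seed(config$seed, held$disease_id, epsilon, Tr)
      w <- train_fn(data[-i], epsilon, Tr, seed_i)
      sigma <- stats::setNames(drop(held$F %*% w), rownames(held$F))
      Y <- high_scoring_set(sigma, score_threshold(sigma, epsilon,
                                                   sigma_max = sum(w)))
      cc <- confusion(Y, held$benchmark)
      r <- r + 1L
      runs[[r]] <- data.frame(
        epsilon = epsilon, Tr = Tr, disease = held$disease_id,
        n_S = length(held$benchmark$S), n_A = length(held$benchmark$A),
        n_Y = length(Y), sensitivity = cc$sensitivity,
        specificity = cc$specificity, accuracy = cc$accuracy,
        stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, runs)
  cells <- do.call(rbind, lapply(
    split(runs, list(runs$epsilon, runs$Tr), drop = TRUE),
    function(cell) data.frame(
      epsilon = cell$epsilon[1], Tr = cell$Tr[1],
      mean_sensitivity = mean(cell$sensitivity),
      mean_specificity = mean(cell$specificity, na.rm = TRUE),
      mean_accuracy = mean(cell$accuracy),
      n_runs = nrow(cell), stringsAsFactors = FALSE)))
  cells <- cells[order(cells$epsilon, cells$Tr), , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(runs = runs, cells = cells), class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat("loocv_report:", nrow(x$runs), "runs over", nrow(x$cells),
      "grid cell(s)\n")
  print(utils::head(x$cells, 10))
  invisible(x)
}

#' Write the LOOCV grid report
#'
#' TSV with per-cell mean sensitivity / specificity / accuracy.
#'
#' @param report a `loocv_report`.
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_grid_report <- function(report, path) {
  write_tsv(report$cells, path)
  invisible(path)
}
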