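#' Read principal-component loadings
#'
#' TSV with columns `chrom, pos, ref, alt, f` (reference-panel alternate
#' allele frequency) and `w_1 .. w_k` (per-component weights).
#'
#' @param path Path to the TSV.
#' @return `data.table` keyed by `packed` with `f` and the weight columns.
#' @export
read_pc_loadings <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(character = "chrom"))
  need <- c("chrom", "pos", "ref", "alt", "f")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("loadings table is missing column(s): ", paste(miss, collapse = ", "))
  wcols <- grep("^w_\\d+$", names(dt), value = TRUE)
  if (length(wcols) == 0L) stop("loadings table has no weight columns (w_1, w_2, ...)")
  if (any(dt$f <= 0 | dt$f >= 1)) stop("loadings f must be strictly inside (0, 1)")
  dt <- .add_variant_keys(dt)
  data.table::setkey(dt, packed)
  dt[]
}

#' Project cohort genotypes onto reference principal components
#'
#' Per-sample coordinates are
#' \deqn{s \cdot \sum_v w_v (g_v - 2 f_v) / \sqrt{2 f_v (1 - f_v)}}
#' over the sample's non-missing loadings variants, where the rescaling
#' \eqn{s = n_{total} / n_{used}} compensates missingness-induced shrinkage.
#' Samples genotyped at fewer than `min_fraction` of the loadings variants are
#' flagged and get `NA` coordinates.
#'
#' @param cohort A `cohort_genotype_matrix`.
#' @param loadings Table from [read_pc_loadings()].
#' @param min_fraction Minimum fraction of loadings variants genotyped;
#'   default 0.8.
#' @return `data.table` with `sample`, `used_fraction`, `flagged`, and
#'   `PC1..PCk` columns.
#' @export
project_onto_pcs <- function(cohort, loadings, min_fraction = 0.8) {
  wcols <- grep("^w_\\d+$", names(loadings), value = TRUE)
  k <- length(wcols)
  hit <- match(loadings$packed, colnames(cohort$dosage))
  present <- !is.na(hit)
  if (!any(present)) stop("no loadings variant is present in the cohort")
  G <- cohort$dosage[, hit[present], drop = FALSE]           # samples x v
  f <- loadings$f[present]
  W <- as.matrix(loadings[present, ..wcols])                 # v x k
  denom <- sqrt(2 * f * (1 - f))
  Z <- sweep(sweep(G, 2L, 2 * f, "-"), 2L, denom, "/")       # standardized dosage
  used <- rowSums(!is.na(Z))
  Z[is.na(Z)] <- 0
  coords <- Z %*% W
  frac <- used / nrow(loadings)
  coords <- coords * ifelse(used > 0, nrow(loadings) / used, NA_real_)
  flagged <- frac < min_fraction
  coords[flagged, ] <- NA_real_
  out <- data.table::data.table(sample = rownames(cohort$dosage),
                                used_fraction = frac, flagged = flagged)
  for (j in seq_len(k)) out[, (paste0("PC", j)) := coords[, j]]
  out[]
}

#' Fit the ancestry random-forest classifier
#'
#' Bagged CART forest with per-node feature subsampling fitted on labelled
#' reference projections; out-of-bag accuracy is reported via `message()`.
#' Deterministic for a fixed seed (set `set.seed()` before calling, or pass
#' `seed`).
#'
#' @param reference_projections `data.table` with `PC1..PCk` columns and a
#'   `label` column of continental ancestry codes.
#' @param seed Optional integer seed.
#' @param ntree Number of trees; default 500.
#' @param mtry Features tried per node; default `floor(sqrt(k))`.
#' @param prob_threshold Minimum winning-class probability for assignment;
#'   default 0.9.
#' @return An `ancestry_model` list with the fitted forest, class labels,
#'   feature names, `prob_threshold` and `oob_accuracy`.
#' @export
fit_ancestry_classifier <- function(reference_projections, seed = NULL, ntree = 500,
                                    mtry = NULL, prob_threshold = 0.9) {
  if (!is.null(seed)) set.seed(seed)
  pccols <- grep("^PC\\d+$", names(reference_projections), value = TRUE)
  lab <- ancestry_label(reference_projections$label)
  if (any(lab == "UNKNOWN")) stop("reference labels must be continental ancestries")
  tab <- table(lab)
  if (length(tab) < 2L) stop("need at least 2 labelled classes")
  low <- names(tab)[tab < 20L]
  if (length(low)) stop("class(es) below the 20-sample floor: ", paste(low, collapse = ", "))
  classes <- sort(names(tab))
  X <- as.matrix(reference_projections[, ..pccols])
  if (anyNA(X)) stop("reference projections contain NA coordinates")
  y <- match(lab, classes) - 1L
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(pccols))))
  fit <- .rf_fit(X, y, length(classes), as.integer(ntree), as.integer(mtry), 5L)
  message(sprintf("ancestry classifier: %d trees, OOB accuracy %.3f",
                  ntree, fit$oob_accuracy))
  structure(list(trees = fit$trees, classes = classes, features = pccols,
                 prob_threshold = prob_threshold, oob_accuracy = fit$oob_accuracy),
            class = "ancestry_model")
}

#' Predict per-class ancestry probabilities
#'
#' @param model An `ancestry_model`.
#' @param projections Table with the model's `PC` columns.
#' @return Matrix (samples x classes) of probabilities summing to 1 per row.
#' @export
predict_ancestry_prob <- function(model, projections) {
  X <- as.matrix(data.table::as.data.table(projections)[, model$features, with = FALSE])
  pr <- .rf_predict(model$trees, X, length(model$classes))
  colnames(pr) <- model$classes
  if ("sample" %in% names(projections)) rownames(pr) <- projections$sample
  pr
}

#' Assign ancestry labels to projected samples
#'
#' The winning class is assigned when its probability reaches the model's
#' `prob_threshold`, otherwise `UNKNOWN`; flagged samples (insufficient
#' genotyped loadings) are `UNKNOWN`; and any assigned group smaller than
#' `min_group_size` individuals is downgraded to `UNKNOWN` so it never enters
#' burden testing.
#'
#' @param projections Output of [project_onto_pcs()].
#' @param model An `ancestry_model`.
#' @param min_group_size Minimum retained group size; default 10.
#' @return `data.table` with `sample`, `ancestry`, `max_prob` and per-class
#'   probability columns.
#' @export
assign_ancestry <- function(projections, model, min_group_size = 10) {
  out <- data.table::data.table(sample = projections$sample)
  ok <- !projections$flagged & stats::complete.cases(
    data.table::as.data.table(projections)[, model$features, with = FALSE])
  pr <- matrix(NA_real_, nrow(out), length(model$classes),
               dimnames = list(out$sample, model$classes))
  if (any(ok)) pr[ok, ] <- predict_ancestry_prob(model, projections[ok])
  maxp <- apply(pr, 1L, function(r) if (all(is.na(r))) NA_real_ else max(r))
  win <- model$classes[apply(pr, 1L, function(r) if (all(is.na(r))) 1L else which.max(r))]
  lab <- ifelse(!is.na(maxp) & maxp >= model$prob_threshold, win, "UNKNOWN")
  small <- names(which(table(lab[lab != "UNKNOWN"]) < min_group_size))
  lab[lab %in% small] <- "UNKNOWN"
  out[, ancestry := lab]
  out[, max_prob := maxp]
  for (cl in model$classes) out[, (cl) := pr[, cl]]
  out[]
}
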