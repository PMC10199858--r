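## Immune-infiltration link: signature scores, uptake correlation,
## phenotype classification, and a small expression simulator.

#' Mean z-score signature over a gene set
#'
#' A deliberately simple surrogate for enrichment-style scoring: each gene
#' is z-scored across samples and the per-sample score is the mean z over
#' the gene set.  Invariant to gene order and to adding a constant to any
#' gene; a gene with zero variance across samples contributes 0 (with a
#' warning).  This is a monotone infiltration readout, not a GSVA
#' reimplementation.
#'
#' @param expr numeric matrix, samples in rows, genes in columns (named).
#' @param gene_set character vector of gene names (subset of columns).
#' @return named numeric vector of per-sample scores.
#' @examples
#' expr <- matrix(rnorm(20), 4, 5,
#'                dimnames = list(paste0("s", 1:4), paste0("g", 1:5)))
#' signatureScore(expr, c("g1", "g2"))
#' @export
signatureScore <- function(expr, gene_set) {
  stopifnot(is.matrix(expr), !is.null(colnames(expr)))
  if (!length(gene_set)) stop("gene_set must be non-empty")
  if (!all(gene_set %in% colnames(expr)))
    stop("gene_set contains genes absent from the expression matrix")
  if (nrow(expr) < 2) stop("need at least 2 samples to z-score")
  sub <- expr[, gene_set, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance gene(s) contribute 0: ",
            paste(gene_set[sds == 0], collapse = ", "))
  }
  z <- sweep(sub, 2, colMeans(sub), "-")
  z <- sweep(z, 2, ifelse(sds > 0, sds, 1), "/")
  z[, sds == 0] <- 0
  rowMeans(z)
}

#' Simulated expression matrix tied to infiltration
#'
#' Generates a samples-by-genes matrix in which the genes of one signature
#' set track a latent infiltration score (plus Gaussian noise) while the
#' background genes are pure noise.  Used to exercise the signature-score
#' and correlation operations against a known ground truth.
#'
#' @param infiltration numeric vector of latent scores (one per sample).
#' @param n_genes total number of genes.
#' @param set_size number of signature genes.
#' @param noise_sd SD of the additive noise on signature genes.
#' @param seed optional seed.
#' @return list with `expr` (matrix) and `gene_set` (character).
#' @examples
#' sim <- simulateExpression(runif(6), seed = 1)
#' signatureScore(sim$expr, sim$gene_set)
#' @export
simulateExpression <- function(infiltration, n_genes = 50, set_size = 10,
                               noise_sd = 0.5, seed = NULL) {
  gen <- function() {
    n <- length(infiltration)
    expr <- matrix(stats::rnorm(n * n_genes), n, n_genes,
                   dimnames = list(
                     if (is.null(names(infiltration)))
                       sprintf("s%d", seq_len(n)) else names(infiltration),
                     sprintf("g%d", seq_len(n_genes))))
    set <- sprintf("g%d", seq_len(set_size))
    expr[, set] <- infiltration +
      matrix(stats::rnorm(n * set_size, 0, noise_sd), n, set_size)
    list(expr = expr, gene_set = set)
  }
  if (is.null(seed)) gen() else .withSeed(seed, gen())
}

#' Spearman correlation between uptake and an immune readout
#'
#' Spearman rank correlation between paired per-patient values (for
#' example mean tumor-to-plasma ratio versus signature score), with an
#' exact permutation p-value for n <= 8 without ties and the t
#' approximation otherwise.
#'
#' @param uptake numeric vector.
#' @param scores numeric vector, same length (>= 3).
#' @return list with `rho`, `p`, `n`, `method`.
#' @examples
#' correlateUptakeInfiltration(c(1, 2, 3, 4, 5), c(2, 3, 1, 5, 4))
#' @export
correlateUptakeInfiltration <- function(uptake, scores) {
  if (length(uptake) != length(scores)) stop("inputs must be paired")
  ok <- is.finite(uptake) & is.finite(scores)
  x <- uptake[ok]; y <- scores[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Spearman correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) || anyDuplicated(y)
  if (n <= 8 && !ties) {
    perms <- .allPermutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t_approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

.allPermutations <- function(n) {
  ## all n! permutations of 1..n as a matrix (n <= 8)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .allPermutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1), n, after = pos - 1),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Classify patients as immune-infiltrated or immune-desert
#'
#' Patients whose mean tumor-to-plasma ratio at 138 h in the tracer-only
#' (4-mg) cycle reaches the threshold are labelled `infiltrated`
#' (>= convention, default threshold 3.0), the rest `desert`.  The
#' tracer-only cycle is used so that saturation effects do not distort the
#' readout.
#'
#' @param mean_ratio named numeric, per-patient mean ratio.
#' @param threshold classification threshold (default 3.0).
#' @return data.frame: patient_id, mean_ratio, label, threshold.
#' @examples
#' classifyPhenotype(c(`1` = 3.2, `6` = 0.83))
#' @export
classifyPhenotype <- function(mean_ratio, threshold = 3.0) {
  if (is.null(threshold)) threshold <- 3.0
  data.frame(patient_id = if (is.null(names(mean_ratio)))
               as.character(seq_along(mean_ratio)) else names(mean_ratio),
             mean_ratio = unname(mean_ratio),
             label = ifelse(mean_ratio >= threshold, "infiltrated", "desert"),
             threshold = threshold)
}

#' Immune summary of a cohort
#'
#' Per-patient mean 138-h tumor-to-plasma ratio in the 4-mg cycle,
#' signature score of a simulated expression matrix driven by the true
#' median lesion infiltration, phenotype label, and mean simulated
#' immunohistochemistry percentage.
#'
#' @param cohort a [PETCohort-class].
#' @param uptake optional precomputed [uptakeTable()] result.
#' @param threshold phenotype threshold.
#' @return data.frame: patient_id, mean_ratio_138h, score, phenotype,
#'   ihc_pct.
#' @examples
#' immuneSummary(generateCohort(CohortConfig(seed = 2)))
#' @export
immuneSummary <- function(cohort, uptake = NULL, threshold = 3.0) {
  stopifnot(is(cohort, "PETCohort"))
  if (is.null(uptake)) uptake <- uptakeTable(cohort)
  sel <- uptake$measure_kind == "tissue_to_plasma" &
    uptake$region_type == "tumor" & uptake$cycle == 1 &
    abs(uptake$time_h - 138) <= 3
  agg <- stats::aggregate(value ~ patient_id, uptake[sel, ], mean)
  ratios <- stats::setNames(agg$value, agg$patient_id)
  infil <- stats::aggregate(infiltration ~ patient_id, cohort@lesions, stats::median)
  ihc <- stats::aggregate(ihc_lag3_pct ~ patient_id, cohort@lesions, mean)
  sim <- simulateExpression(
    stats::setNames(infil$infiltration, infil$patient_id),
    seed = cohort@provenance$seed + 1L)
  sc <- signatureScore(sim$expr, sim$gene_set)
  ph <- classifyPhenotype(ratios, threshold)
  out <- data.frame(patient_id = ph$patient_id,
                    mean_ratio_138h = ph$mean_ratio,
                    phenotype = ph$label)
  out$score <- sc[out$patient_id]
  out$ihc_pct <- stats::setNames(ihc$ihc_lag3_pct, ihc$patient_id)[out$patient_id]
  out
}
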