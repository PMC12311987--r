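#' Genotype dosage table
#'
#' Subjects-by-SNPs dosage matrix with marker metadata. Dosages are either
#' binary carrier coding (`{0, 1}`) or additive allele counts (`{0, 1, 2}`).
#' Missing dosages are imputed to the per-SNP modal value at construction
#' time, mirroring the usual pre-analysis imputation step.
#'
#' @param dosages numeric `n x N_G` matrix (rownames = subject ids).
#' @param snp_ids,chromosomes,positions optional marker metadata vectors of
#'   length `N_G`.
#' @param coding `"binary"` or `"additive"`.
#' @return An object of class `genotype_table` with fields `dosages`,
#'   `snp_ids`, `chromosomes`, `positions`, `allele_frequencies`, `coding`.
#' @export
genotype_table <- function(dosages, snp_ids = colnames(dosages),
                           chromosomes = NULL, positions = NULL,
                           coding = c("binary", "additive")) {
  coding <- match.arg(coding)
  dosages <- as.matrix(dosages)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosages)))
  if (anyNA(dosages)) {
    for (g in seq_len(ncol(dosages))) {
      miss <- is.na(dosages[, g])
      if (any(miss)) {
        obs <- dosages[!miss, g]
        if (!length(obs)) stop("SNP ", snp_ids[g], " entirely missing")
        tab <- table(obs)
        dosages[miss, g] <- as.numeric(names(tab)[which.max(tab)])
      }
    }
  }
  maxdose <- if (coding == "binary") 1 else 2
  if (any(dosages < 0 | dosages > maxdose))
    stop("dosages outside the declared ", coding, " coding {0..", maxdose, "}")
  af <- colMeans(dosages) / maxdose
  colnames(dosages) <- snp_ids
  structure(list(dosages = dosages, snp_ids = snp_ids,
                 chromosomes = chromosomes, positions = positions,
                 allele_frequencies = af, coding = coding),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table>", nrow(x$dosages), "subjects x",
      ncol(x$dosages), "SNPs (", x$coding, "coding )\n")
  invisible(x)
}

#' Per-SNP linear association model
#'
#' Ordinary least squares of the outcome on one SNP dosage plus covariates,
#' \eqn{y_i = x_{ig}\nu_g + c_i^\top u_g + \epsilon_i}, with a two-sided
#' t-test on the genetic effect \eqn{\nu_g}.
#'
#' @param y numeric outcome vector.
#' @param x_g numeric dosage vector.
#' @param C covariate matrix including an intercept column.
#' @return List with `effect`, `se`, `p`, `df`, and `monomorphic` (TRUE when
#'   the SNP carries no variation, in which case the estimates are `NA`).
#' @export
fit_snp_model <- function(y, x_g, C) {
  n <- length(y)
  C <- as.matrix(C)
  if (nrow(C) != n || length(x_g) != n) stop("subject-count mismatch")
  if (qr(C)$rank < ncol(C)) stop("rank-deficient covariate matrix")
  if (var(x_g) < .Machine$double.eps)
    return(list(effect = NA_real_, se = NA_real_, p = NA_real_,
                df = NA_integer_, monomorphic = TRUE))
  X <- cbind(x_g = x_g, C)
  fit <- lm.fit(X, y)
  df <- n - fit$rank
  rss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(XtXinv[1, 1] * rss / max(df, 1L))
  eff <- fit$coefficients[["x_g"]]
  p <- if (df > 0 && se > 0) 2 * pt(abs(eff / se), df, lower.tail = FALSE)
       else if (df > 0 && rss == 0) 0 else NA_real_
  list(effect = eff, se = se, p = p, df = df, monomorphic = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"`). Adjusted values are monotone
#' and capped at 1; `NA` input p-values propagate as `NA`.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Genome-wide per-SNP screen with FDR selection
#'
#' Fits the per-SNP linear model for every marker, applies Benjamini-Hochberg
#' adjustment across markers, and flags SNPs whose adjusted p-value is at or
#' below `q_threshold` as the candidate set for mediation analysis. The fit is
#' vectorized by residualizing the outcome and each dosage on the covariates
#' (Frisch-Waugh-Lovell), which is algebraically identical to the per-SNP
#' regression.
#'
#' @param y numeric outcome vector.
#' @param genotypes a [genotype_table()] (or plain dosage matrix).
#' @param C covariate matrix including an intercept.
#' @param q_threshold FDR level for selection (default 0.05).
#' @return A `data.frame` of class `screen_result` with columns `snp`, `chr`,
#'   `pos`, `freq`, `effect`, `se`, `p`, `p_adj`, `selected`, `monomorphic`.
#' @export
genome_screen <- function(y, genotypes, C, q_threshold = 0.05) {
  if (!inherits(genotypes, "genotype_table"))
    genotypes <- genotype_table(as.matrix(genotypes),
                                coding = if (max(genotypes, na.rm = TRUE) > 1)
                                  "additive" else "binary")
  X <- genotypes$dosages
  n <- length(y)
  if (nrow(X) != n) stop("subject-count mismatch between outcome and genotypes")
  C <- as.matrix(C)
  if (nrow(C) != n) stop("subject-count mismatch between outcome and covariates")
  if (qr(C)$rank < ncol(C)) stop("rank-deficient covariate matrix")
  pc <- ncol(C)
  # residualize on covariates once; per-SNP slope then from simple regression
  H <- C %*% chol2inv(chol(crossprod(C))) %*% t(C)
  ry <- y - H %*% y
  rX <- X - H %*% X
  sxx <- colSums(rX^2)
  mono <- sxx < n * .Machine$double.eps
  sxx[mono] <- NA_real_
  eff <- as.numeric(crossprod(rX, ry)) / sxx
  df <- n - pc - 1L
  rss <- sum(ry^2) - eff^2 * sxx
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df / sxx)
  tval <- eff / se
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  p[which(!mono & rss == 0)] <- 0
  p_adj <- bh_adjust(p)
  out <- data.frame(
    snp = genotypes$snp_ids,
    chr = if (is.null(genotypes$chromosomes)) NA else genotypes$chromosomes,
    pos = if (is.null(genotypes$positions)) NA else genotypes$positions,
    freq = genotypes$allele_frequencies,
    effect = eff, se = se, p = p, p_adj = p_adj,
    selected = !is.na(p_adj) & p_adj <= q_threshold,
    monomorphic = mono,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("screen_result", "data.frame")
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>", nrow(x), "SNPs;", sum(x$selected), "selected\n")
  print.data.frame(head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
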