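#' Read landmark contours from a long-format table
#'
#' Expects columns `subject_id`, `point_index`, `x`, `y`; points are assumed
#' ordered along the contour within subject (rows are sorted by
#' `point_index`). CSV or TSV is detected from the file extension.
#'
#' @param path file path.
#' @return List of [landmark_curve()] objects, one per subject, in order of
#'   first appearance.
#' @export
read_landmarks <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("subject_id", "point_index", "x", "y")
  if (!all(need %in% names(d)))
    stop("landmark file must have columns: ", paste(need, collapse = ", "))
  ids <- unique(d$subject_id)
  lapply(ids, function(id) {
    di <- d[d$subject_id == id, ]
    di <- di[order(di$point_index), ]
    landmark_curve(cbind(di$x, di$y), subject_id = as.character(id))
  })
}

#' Write aligned SRVFs to CSV
#'
#' Long format with columns `subject_id`, `s`, `q1`, `q2`.
#'
#' @param alignment result of [align_cohort()].
#' @param path output file path.
#' @export
write_aligned_srvfs <- function(alignment, path) {
  n <- dim(alignment$M)[1]; T <- dim(alignment$M)[2]
  d <- data.frame(
    subject_id = rep(alignment$subject_ids, each = T),
    s = rep(alignment$grid, n),
    q1 = as.numeric(t(alignment$M[, , 1])),
    q2 = as.numeric(t(alignment$M[, , 2])))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read aligned SRVFs written by [write_aligned_srvfs()]
#'
#' @param path CSV path with columns `subject_id`, `s`, `q1`, `q2`.
#' @return List with `M` (`n x T x 2`), `grid`, `subject_ids`.
#' @export
read_aligned_srvfs <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(d$subject_id)
  grid <- d$s[d$subject_id == ids[1]]
  T <- length(grid); n <- length(ids)
  M <- array(NA_real_, c(n, T, 2L), dimnames = list(ids, NULL, c("q1", "q2")))
  for (i in seq_len(n)) {
    di <- d[d$subject_id == ids[i], ]
    M[i, , 1] <- di$q1; M[i, , 2] <- di$q2
  }
  list(M = M, grid = grid, subject_ids = as.character(ids))
}

#' Read a genotype dosage table
#'
#' Supports PLINK `.raw`-style exports (whitespace-separated, with `IID` and
#' optional `FID/PAT/MAT/SEX/PHENOTYPE` columns followed by one column per
#' SNP) and plain CSV dosage matrices whose first column is the subject id.
#'
#' @param path file path (`.raw` or `.csv`).
#' @param coding `"binary"` or `"additive"`.
#' @return A [genotype_table()]; subject ids become the dosage rownames.
#' @export
read_genotypes <- function(path, coding = c("additive", "binary")) {
  coding <- match.arg(coding)
  if (grepl("\\.raw$", path, ignore.case = TRUE)) {
    d <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
    meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                      names(d))
    ids <- if ("IID" %in% names(d)) as.character(d$IID)
           else as.character(seq_len(nrow(d)))
    X <- as.matrix(d[, setdiff(names(d), meta), drop = FALSE])
  } else {
    d <- read.csv(path, stringsAsFactors = FALSE)
    ids <- as.character(d[[1]])
    X <- as.matrix(d[, -1, drop = FALSE])
  }
  rownames(X) <- ids
  genotype_table(X, coding = coding)
}

#' Read a phenotype/covariate table keyed by subject id
#'
#' @param path CSV with a `subject_id` column plus outcome/covariate columns.
#' @return A `data.frame` with `subject_id` coerced to character.
#' @export
read_phenotypes <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(d))
    stop("phenotype file must have a subject_id column")
  d$subject_id <- as.character(d$subject_id)
  d
}

#' Write a screening report to CSV
#'
#' Columns: `snp`, `chr`, `pos`, `freq`, `effect`, `se`, `p`, `p_adj`,
#' `selected`.
#'
#' @param screen a `screen_result` from [genome_screen()].
#' @param path output CSV path.
#' @export
write_screen_result <- function(screen, path) {
  write.csv(as.data.frame(screen), path, row.names = FALSE)
  invisible(path)
}

#' Write a fitted mediation model to disk
#'
#' Scalars (`gamma`, `kappa`, the FPCA dimension, and the causal estimands)
#' go to a JSON file; the coefficient functions (`alpha_j`, `beta_j`, SAIE)
#' go to a CSV by grid point.
#'
#' @param fit a `shape_mediation` fit.
#' @param json_path,csv_path output file paths.
#' @export
write_mediation_fit <- function(fit, json_path, csv_path) {
  e <- fit$effects
  scalars <- list(snp = e$snp_id, outcome = e$outcome_name,
                  gamma = fit$fit_outcome$gamma,
                  kappa = as.numeric(fit$fit_outcome$kappa),
                  K = fit$fit_outcome$K,
                  ade = e$ade, aie = e$aie, ate = e$ate, mp = e$mp)
  jsonlite::write_json(scalars, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  a <- fit$fit_mediator$alpha
  b <- fit$fit_outcome$beta
  d <- data.frame(s = e$grid, alpha1 = a[, 1], alpha2 = a[, 2],
                  beta1 = b[, 1], beta2 = b[, 2], saie = e$saie)
  write.csv(d, csv_path, row.names = FALSE)
  invisible(list(json = json_path, csv = csv_path))
}

#' Write a causal-effect report to CSV
#'
#' One row per SNP-outcome pair with ATE, ADE, AIE, the AIE confidence
#' interval, the mediation proportion, and a passthrough gene annotation.
#'
#' @param fits list of `shape_mediation` fits (with bootstrap intervals).
#' @param path output CSV path.
#' @param genes optional character vector of gene annotations (passthrough
#'   metadata; not computed).
#' @return The report `data.frame`, invisibly written to `path`.
#' @export
write_effects_report <- function(fits, path, genes = NULL) {
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]; e <- f$effects
    ci <- if (!is.null(f$intervals)) f$intervals$aie else c(NA_real_, NA_real_)
    data.frame(outcome = e$outcome_name, snp = e$snp_id,
               ate = e$ate, ade = e$ade, aie = e$aie,
               aie_lower = ci[1], aie_upper = ci[2],
               mp = e$mp,
               significant = if (!is.null(f$significant))
                 f$significant[["aie"]] else NA,
               gene = if (is.null(genes)) NA_character_ else genes[i],
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  write.csv(report, path, row.names = FALSE)
  invisible(report)
}

#' Write a per-SNP SAIE band file
#'
#' Columns: `s`, `saie`, `band_lower`, `band_upper`, `significant`.
#'
#' @param fit a `shape_mediation` fit with a bootstrap band.
#' @param path output CSV path.
#' @export
write_saie_band <- function(fit, path) {
  if (is.null(fit$band)) stop("fit has no bootstrap band")
  d <- data.frame(s = fit$effects$grid, saie = fit$effects$saie,
                  band_lower = fit$band$lower, band_upper = fit$band$upper,
                  significant = fit$subregions$mask)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
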