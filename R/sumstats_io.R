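#' Default column mapping for GWAS summary-statistics files
#'
#' Maps the internal field names used throughout the package to the column
#' headers conventionally found in GWAS summary-statistics exports.
#'
#' @return Named character vector: names are internal fields
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`), values are the file column headers
#'   (`SNP`, `CHR`, `BP`, `EA`, `OA`, `EAF`, `BETA`, `SE`, `P`, `N`).
#' @export
default_gwas_columns <- function() {
  c(variant_id = "SNP", chrom = "CHR", pos = "BP",
    effect_allele = "EA", other_allele = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", pval = "P", n = "N")
}

.gwas_required_fields <- c("variant_id", "chrom", "pos", "effect_allele",
                           "other_allele", "beta", "se", "pval")
.gwas_optional_fields <- c("eaf", "n")
.gwas_fields <- c(.gwas_required_fields[1:5], "eaf",
                  .gwas_required_fields[6:8], "n")
.valid_alleles <- c("A", "C", "G", "T")

#' Validate rows of GWAS summary-association records
#'
#' Checks every row against the per-record invariants: standard error
#' strictly positive, alleles single bases in A/C/G/T and distinct, effect
#' allele frequency (when present) in \[0, 1\], p-value in (0, 1\], position a
#' positive number and beta finite. Rows violating any invariant are
#' separated out with the reason recorded; they are never silently dropped.
#'
#' @param records Data frame with (at least) the internal fields
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `se`, `pval`, and optionally `eaf` and `n`.
#' @return List with `records` (the valid rows), `n_rejected`, and
#'   `reject_log` (data frame of `variant_id`, `reason`).
#' @export
validate_gwas_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.gwas_required_fields, names(records))
  if (length(missing_cols) > 0) {
    stop("missing required field(s): ", paste(missing_cols, collapse = ", "))
  }
  for (f in .gwas_optional_fields) {
    if (!f %in% names(records)) records[[f]] <- NA_real_
  }
  records <- records[, .gwas_fields, drop = FALSE]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (f in c("pos", "eaf", "beta", "se", "pval", "n")) {
    records[[f]] <- as.numeric(records[[f]])
  }

  reason <- rep(NA_character_, nrow(records))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    ifelse(is.na(reason) & bad, why, reason)
  }
  reason <- flag(!(records$se > 0) | !is.finite(records$se), "se must be > 0")
  reason <- flag(!(records$effect_allele %in% .valid_alleles) |
                   !(records$other_allele %in% .valid_alleles),
                 "alleles must be single bases A/C/G/T")
  reason <- flag(records$effect_allele == records$other_allele,
                 "effect and other allele must differ")
  reason <- flag(!is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1),
                 "eaf must be in [0, 1]")
  reason <- flag(!(records$pval > 0 & records$pval <= 1), "pval must be in (0, 1]")
  reason <- flag(!(records$pos > 0) | !is.finite(records$pos),
                 "pos must be a positive coordinate")
  reason <- flag(!is.finite(records$beta), "beta must be finite")

  ok <- is.na(reason)
  list(records = records[ok, , drop = FALSE],
       n_rejected = sum(!ok),
       reject_log = data.frame(variant_id = records$variant_id[!ok],
                               reason = reason[!ok],
                               stringsAsFactors = FALSE))
}

#' Construct a summary-statistics dataset for one trait
#'
#' @param trait_name Character label for the trait.
#' @param trait_type Either `"exposure"` or `"outcome"`.
#' @param records Data frame of per-variant summary associations (internal
#'   field names; see [validate_gwas_records()]). All rows must satisfy the
#'   record invariants and `variant_id` must be unique.
#' @return Object of class `summary_dataset`: a list with `trait_name`,
#'   `trait_type`, `records`.
#' @export
summary_dataset <- function(trait_name, trait_type = c("exposure", "outcome"),
                            records) {
  trait_type <- match.arg(trait_type)
  v <- validate_gwas_records(records)
  if (v$n_rejected > 0) {
    stop("invalid record(s): ",
         paste(unique(v$reject_log$reason), collapse = "; "))
  }
  dup <- v$records$variant_id[duplicated(v$records$variant_id)]
  if (length(dup) > 0) {
    stop("duplicate variant_id: ", paste(unique(dup), collapse = ", "))
  }
  rownames(v$records) <- NULL
  structure(list(trait_name = trait_name, trait_type = trait_type,
                 records = v$records, n_rejected = 0L,
                 reject_log = v$reject_log),
            class = "summary_dataset")
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s): %d variants\n",
              x$trait_name, x$trait_type, nrow(x$records)))
  invisible(x)
}

# Coerce the containers that carry per-variant exposure records to a plain
# records data frame.
as_records <- function(x) {
  if (inherits(x, "summary_dataset")) return(x$records)
  if (inherits(x, "instrument_set")) return(x$selected)
  if (is.data.frame(x)) return(x)
  stop("cannot extract GWAS records from object of class ",
       paste(class(x), collapse = "/"))
}

trait_name_of <- function(x, fallback) {
  if (inherits(x, "summary_dataset")) return(x$trait_name)
  if (inherits(x, "instrument_set") && !is.null(x$trait_name)) return(x$trait_name)
  fallback
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Reads a tab-separated file with a header row, maps columns through
#' `column_map`, upper-cases alleles, and validates every row. Rows failing
#' the record invariants are rejected and counted (reported via a message and
#' stored on the returned object); duplicated variant identifiers among the
#' valid rows are an error.
#'
#' Missing values are encoded as `NA`; `eaf` and `n` columns are optional.
#'
#' @param path File path.
#' @param trait_name Trait label; defaults to the file name.
#' @param trait_type `"exposure"` or `"outcome"`.
#' @param column_map Named character vector mapping internal fields to file
#'   headers, as produced by [default_gwas_columns()].
#' @return A `summary_dataset`; elements `n_rejected` and `reject_log`
#'   account for every discarded input row.
#' @export
read_sumstats <- function(path, trait_name = basename(path),
                          trait_type = c("exposure", "outcome"),
                          column_map = default_gwas_columns()) {
  trait_type <- match.arg(trait_type)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), check.names = FALSE)
  need <- column_map[.gwas_required_fields]
  absent <- need[!need %in% names(raw)]
  if (length(absent) > 0) {
    stop("format error: missing required column(s): ",
         paste(absent, collapse = ", "))
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in .gwas_fields) {
    col <- column_map[[f]]
    df[[f]] <- if (!is.null(col) && col %in% names(raw)) raw[[col]] else NA
  }
  v <- validate_gwas_records(df)
  dup <- v$records$variant_id[duplicated(v$records$variant_id)]
  if (length(dup) > 0) {
    stop("validation error: duplicate variant_id: ",
         paste(unique(dup), collapse = ", "))
  }
  if (v$n_rejected > 0) {
    message(sprintf("%s: rejected %d of %d rows failing record invariants",
                    path, v$n_rejected, nrow(raw)))
  }
  ds <- summary_dataset(trait_name, trait_type, v$records)
  ds$n_rejected <- v$n_rejected
  ds$reject_log <- v$reject_log
  ds
}

#' Write a summary-statistics dataset to a tab-delimited file
#'
#' Inverse of [read_sumstats()]: tab-separated, `.` decimal separator, `NA`
#' for missing values, columns named through `column_map`.
#'
#' @inheritParams read_sumstats
#' @param dataset A `summary_dataset`.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(dataset, path, column_map = default_gwas_columns()) {
  rec <- as_records(dataset)
  out <- rec[, .gwas_fields, drop = FALSE]
  names(out) <- column_map[.gwas_fields]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Construct an LD reference
#'
#' @param variant_ids Character vector of variant identifiers.
#' @param r2 Square matrix of squared correlations, entries in \[0, 1\],
#'   symmetric to within `tol`, unit diagonal.
#' @param pos Optional numeric vector of per-variant positions.
#' @param tol Maximum tolerated asymmetry before the input is rejected.
#' @return Object of class `ld_reference` with exactly symmetric `r2`.
#' @export
ld_reference <- function(variant_ids, r2, pos = NULL, tol = 1e-8) {
  variant_ids <- as.character(variant_ids)
  r2 <- as.matrix(r2)
  k <- length(variant_ids)
  if (!all(dim(r2) == c(k, k))) stop("r2 must be ", k, "x", k)
  if (anyDuplicated(variant_ids)) stop("duplicate variant_id in LD reference")
  if (max(abs(r2 - t(r2))) > tol) {
    stop("validation error: r2 matrix asymmetric beyond ", format(tol))
  }
  if (any(r2 < -tol | r2 > 1 + tol)) stop("r2 entries must be in [0, 1]")
  if (max(abs(diag(r2) - 1)) > tol) stop("r2 diagonal must be 1")
  r2 <- (r2 + t(r2)) / 2
  r2[r2 < 0] <- 0
  r2[r2 > 1] <- 1
  diag(r2) <- 1
  dimnames(r2) <- list(variant_ids, variant_ids)
  if (!is.null(pos)) {
    pos <- as.numeric(pos)
    if (length(pos) != k) stop("pos must match variant_ids")
    names(pos) <- variant_ids
  }
  structure(list(variant_ids = variant_ids, r2 = r2, pos = pos),
            class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("<ld_reference> %d variants\n", length(x$variant_ids)))
  invisible(x)
}

#' Read an LD reference from a tab-delimited file
#'
#' Accepts either a square-matrix layout (first column `SNP` holding variant
#' ids, remaining columns one per variant) or a pairwise long layout with
#' columns `id1`, `id2`, `r2`. Long input is symmetrized; pairs absent from
#' the file default to r-squared 0 and the diagonal is 1.
#'
#' @param path File path.
#' @return An `ld_reference`.
#' @export
read_ld <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) == 3 && all(tolower(names(raw)) == c("id1", "id2", "r2"))) {
    ids <- sort(unique(c(as.character(raw[[1]]), as.character(raw[[2]]))))
    k <- length(ids)
    m <- matrix(0, k, k, dimnames = list(ids, ids))
    i <- match(as.character(raw[[1]]), ids)
    j <- match(as.character(raw[[2]]), ids)
    val <- as.numeric(raw[[3]])
    # check that duplicated/reciprocal pairs agree before symmetrizing
    seen <- matrix(NA_real_, k, k)
    for (r in seq_along(i)) {
      a <- min(i[r], j[r]); b <- max(i[r], j[r])
      if (!is.na(seen[a, b]) && abs(seen[a, b] - val[r]) > 1e-8) {
        stop("validation error: conflicting r2 for pair ",
             ids[a], "/", ids[b])
      }
      seen[a, b] <- val[r]
      m[a, b] <- val[r]
      m[b, a] <- val[r]
    }
    diag(m) <- 1
    return(ld_reference(ids, m))
  }
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (!identical(colnames(m), ids)) {
    stop("format error: square LD matrix header must match the id column")
  }
  ld_reference(ids, m)
}

#' Write an LD reference to a tab-delimited file
#'
#' @param ld An `ld_reference`.
#' @param path File path.
#' @param format `"matrix"` (square, id column `SNP`) or `"long"`
#'   (`id1`, `id2`, `r2`; upper triangle including only nonzero pairs).
#' @return Invisibly, `path`.
#' @export
write_ld <- function(ld, path, format = c("matrix", "long")) {
  format <- match.arg(format)
  if (format == "matrix") {
    df <- data.frame(SNP = ld$variant_ids, ld$r2, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(upper.tri(ld$r2) & ld$r2 != 0, arr.ind = TRUE)
    df <- data.frame(id1 = ld$variant_ids[idx[, 1]],
                     id2 = ld$variant_ids[idx[, 2]],
                     r2 = ld$r2[idx])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# Pairwise r2 lookup; variants absent from the reference are treated as
# uncorrelated (r2 = 0), which instrument selection reports as a warning.
r2_between <- function(ld, id1, id2) {
  if (is.null(ld)) return(0)
  i <- match(id1, ld$variant_ids)
  j <- match(id2, ld$variant_ids)
  if (is.na(i) || is.na(j)) return(0)
  ld$r2[i, j]
}

#' Read a confounder-annotation table
#'
#' Tab-delimited with columns `SNP`, `TRAIT`, `CATEGORY`, `P`: one row per
#' reported variant-trait association (the offline stand-in for a
#' PhenoScanner lookup). P-values must lie in (0, 1\].
#'
#' @param path File path.
#' @return Data frame with fields `variant_id`, `trait`, `category`, `pval`.
#' @export
read_annotations <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("SNP", "TRAIT", "CATEGORY", "P")
  absent <- setdiff(need, names(raw))
  if (length(absent) > 0) {
    stop("format error: missing required column(s): ",
         paste(absent, collapse = ", "))
  }
  ann <- data.frame(variant_id = as.character(raw$SNP),
                    trait = as.character(raw$TRAIT),
                    category = as.character(raw$CATEGORY),
                    pval = as.numeric(raw$P),
                    stringsAsFactors = FALSE)
  bad <- !(ann$pval > 0 & ann$pval <= 1)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) stop("validation error: annotation pval must be in (0, 1]")
  ann
}

#' Write a confounder-annotation table
#'
#' @param annotations Data frame with `variant_id`, `trait`, `category`,
#'   `pval` (as returned by [read_annotations()] or
#'   [simulate_annotations()]).
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  out <- data.frame(SNP = annotations$variant_id, TRAIT = annotations$trait,
                    CATEGORY = annotations$category, P = annotations$pval)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.results_columns <- c("exposure", "outcome", "nSNPs", "method", "beta", "ci",
                      "se", "pval", "q_stat", "q_pval", "egger_intercept",
                      "egger_intercept_pval", "presso_pval")

#' Write an MR results table
#'
#' One row per exposure-by-outcome-by-method combination, in a fixed
#' 13-column layout mirroring published main-result and sensitivity tables:
#' `exposure`, `outcome`, `nSNPs`, `method`, `beta`, `ci` (the 95% interval
#' as `"low,high"`), `se`, `pval`, `q_stat`, `q_pval`, `egger_intercept`,
#' `egger_intercept_pval`, `presso_pval`.
#'
#' @param results An `mr_grid` object or a results data frame (as from
#'   [as.data.frame.mr_grid()]).
#' @param path File path.
#' @param digits Optional number of significant digits for numeric columns;
#'   `NULL` writes full precision (round-trip safe).
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path, digits = NULL) {
  df <- if (inherits(results, "mr_grid")) as.data.frame(results) else results
  if (!is.data.frame(df) || nrow(df) == 0) stop("results must be non-empty")
  fmt <- function(x) {
    if (!is.null(digits)) x <- signif(x, digits)
    ifelse(is.na(x), "NA", sprintf("%.17g", x))
  }
  out <- data.frame(exposure = df$exposure, outcome = df$outcome,
                    nSNPs = df$n_snps, method = df$method,
                    beta = fmt(df$theta),
                    ci = paste(fmt(df$ci_low), fmt(df$ci_high), sep = ","),
                    se = fmt(df$se), pval = fmt(df$pval),
                    q_stat = fmt(df$q_stat), q_pval = fmt(df$q_pval),
                    egger_intercept = fmt(df$egger_intercept),
                    egger_intercept_pval = fmt(df$egger_intercept_pval),
                    presso_pval = fmt(df$presso_pval),
                    stringsAsFactors = FALSE)
  stopifnot(identical(names(out), .results_columns))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read back an MR results table written by [write_results()]
#'
#' @param path File path.
#' @return Data frame with the `ci` column split back into numeric `ci_low`
#'   and `ci_high`.
#' @export
read_results <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  absent <- setdiff(.results_columns, names(raw))
  if (length(absent) > 0) {
    stop("format error: missing column(s): ", paste(absent, collapse = ", "))
  }
  ci <- strsplit(raw$ci, ",", fixed = TRUE)
  num <- function(x) suppressWarnings(as.numeric(x))
  data.frame(exposure = raw$exposure, outcome = raw$outcome,
             n_snps = as.integer(raw$nSNPs), method = raw$method,
             theta = num(raw$beta),
             ci_low = num(vapply(ci, `[`, "", 1)),
             ci_high = num(vapply(ci, `[`, "", 2)),
             se = num(raw$se), pval = num(raw$pval),
             q_stat = num(raw$q_stat), q_pval = num(raw$q_pval),
             egger_intercept = num(raw$egger_intercept),
             egger_intercept_pval = num(raw$egger_intercept_pval),
             presso_pval = num(raw$presso_pval),
             stringsAsFactors = FALSE)
}
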