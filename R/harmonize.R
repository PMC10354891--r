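.complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Is a variant palindromic (A/T or C/G)?
#'
#' @param effect_allele,other_allele Single-base allele codes.
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  unname(.complement[effect_allele] == other_allele)
}

.kept_statuses <- c("aligned", "flipped", "palindromic_kept")

#' Harmonize one exposure/outcome record pair to a common effect allele
#'
#' Aligns the outcome association to the exposure's effect allele. Matching
#' allele labels keep the outcome effect as is; swapped labels flip the sign
#' of the outcome beta and complement its allele frequency; when direct and
#' swapped comparisons both fail, the outcome alleles are strand-flipped
#' (complemented) and compared again. Palindromic variants (A/T, C/G), whose
#' strand cannot be resolved from labels, are aligned by effect-allele
#' frequency when both frequencies fall outside the ambiguity window, and
#' dropped otherwise. Irreconcilable allele pairs are dropped as
#' incompatible. Drops are statuses, never errors.
#'
#' @param exp_record,out_record Single-row records data frames for the same
#'   `variant_id`.
#' @param palindrome_window Open frequency interval treated as ambiguous for
#'   palindromes.
#' @param palindrome_policy `"infer"` or `"drop"` (drop every palindrome).
#' @return One-row data frame with `variant_id`, `effect_allele`,
#'   `other_allele`, `beta_exposure`, `se_exposure`, `eaf_exposure`,
#'   `pval_exposure`, `beta_outcome`, `se_outcome`, `eaf_outcome`, `status`
#'   (`aligned`, `flipped`, `palindromic_kept`, `dropped_palindromic`, or
#'   `dropped_incompatible`).
#' @export
harmonize_pair <- function(exp_record, out_record,
                           palindrome_window = c(0.42, 0.58),
                           palindrome_policy = c("infer", "drop")) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(exp_record$variant_id == out_record$variant_id)
  ea_x <- exp_record$effect_allele
  oa_x <- exp_record$other_allele
  ea_y <- out_record$effect_allele
  oa_y <- out_record$other_allele
  by <- out_record$beta
  eaf_y <- out_record$eaf

  res <- function(status, beta_outcome = by, eaf_outcome = eaf_y) {
    data.frame(variant_id = exp_record$variant_id,
               effect_allele = ea_x, other_allele = oa_x,
               beta_exposure = exp_record$beta, se_exposure = exp_record$se,
               eaf_exposure = exp_record$eaf, pval_exposure = exp_record$pval,
               beta_outcome = beta_outcome, se_outcome = out_record$se,
               eaf_outcome = eaf_outcome, status = status,
               stringsAsFactors = FALSE)
  }

  if (is_palindromic(ea_x, oa_x)) {
    same_pair <- setequal(c(ea_x, oa_x), c(ea_y, oa_y))
    if (!same_pair) return(res("dropped_incompatible"))
    if (palindrome_policy == "drop") return(res("dropped_palindromic"))
    eaf_x <- exp_record$eaf
    if (is.na(eaf_x) || is.na(eaf_y)) return(res("dropped_palindromic"))
    # align by label first, then check strand agreement via frequencies
    if (ea_y != ea_x) {
      by <- -by
      eaf_y <- 1 - eaf_y
    }
    ambiguous <- function(f) f > palindrome_window[1] & f < palindrome_window[2]
    if (ambiguous(eaf_x) || ambiguous(eaf_y)) {
      return(res("dropped_palindromic"))
    }
    if ((eaf_x - 0.5) * (eaf_y - 0.5) < 0) {
      # frequencies disagree: the outcome record is on the other strand
      by <- -by
      eaf_y <- 1 - eaf_y
    }
    return(res("palindromic_kept", by, eaf_y))
  }

  if (ea_y == ea_x && oa_y == oa_x) return(res("aligned"))
  if (ea_y == oa_x && oa_y == ea_x) {
    return(res("flipped", -by, if (is.na(eaf_y)) NA_real_ else 1 - eaf_y))
  }
  ea_yc <- unname(.complement[ea_y])
  oa_yc <- unname(.complement[oa_y])
  if (!is.na(ea_yc) && !is.na(oa_yc)) {
    if (ea_yc == ea_x && oa_yc == oa_x) return(res("aligned"))
    if (ea_yc == oa_x && oa_yc == ea_x) {
      return(res("flipped", -by, if (is.na(eaf_y)) NA_real_ else 1 - eaf_y))
    }
  }
  res("dropped_incompatible")
}

#' Harmonize exposure and outcome datasets over their shared variants
#'
#' Applies [harmonize_pair()] to every variant in the id-intersection of the
#' two datasets, in deterministic `variant_id` order. Kept pairs (statuses
#' `aligned`, `flipped`, `palindromic_kept`) form the analysis set; dropped
#' pairs are fully accounted for in the drop log, so
#' `nrow(pairs) + nrow(drop_log)` equals the intersection size.
#'
#' @param exposure Exposure `summary_dataset`, `instrument_set`, or records
#'   data frame.
#' @param outcome Outcome `summary_dataset` or records data frame.
#' @param palindrome_window,palindrome_policy See [harmonize_pair()].
#' @param exposure_name,outcome_name Trait labels (defaulted from the
#'   datasets when available).
#' @return Object of class `harmonized_set`: `exposure_name`,
#'   `outcome_name`, `pairs` (kept rows), `drop_log`. An empty intersection
#'   yields zero-row components, not an error.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_window = c(0.42, 0.58),
                      palindrome_policy = c("infer", "drop"),
                      exposure_name = NULL, outcome_name = NULL) {
  palindrome_policy <- match.arg(palindrome_policy)
  erec <- as_records(exposure)
  orec <- as_records(outcome)
  if (is.null(exposure_name)) exposure_name <- trait_name_of(exposure, "exposure")
  if (is.null(outcome_name)) outcome_name <- trait_name_of(outcome, "outcome")
  ids <- sort(intersect(erec$variant_id, orec$variant_id))
  rows <- lapply(ids, function(v) {
    harmonize_pair(erec[erec$variant_id == v, , drop = FALSE],
                   orec[orec$variant_id == v, , drop = FALSE],
                   palindrome_window, palindrome_policy)
  })
  all_rows <- if (length(rows) > 0) do.call(rbind, rows) else
    harmonize_pair(
      data.frame(variant_id = "x", effect_allele = "A", other_allele = "G",
                 beta = 0, se = 1, eaf = NA_real_, pval = 1),
      data.frame(variant_id = "x", effect_allele = "A", other_allele = "G",
                 beta = 0, se = 1, eaf = NA_real_, pval = 1))[0, ]
  kept <- all_rows$status %in% .kept_statuses
  pairs <- all_rows[kept, , drop = FALSE]
  drop_log <- all_rows[!kept, , drop = FALSE]
  rownames(pairs) <- NULL
  rownames(drop_log) <- NULL
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 pairs = pairs, drop_log = drop_log),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d pairs (%d dropped)\n",
              x$exposure_name, x$outcome_name, nrow(x$pairs),
              nrow(x$drop_log)))
  invisible(x)
}

# Coerce a harmonized_set or compatible data frame to the pairs table the
# estimators consume (beta_exposure/se_exposure/beta_outcome/se_outcome).
as_pairs <- function(x) {
  p <- if (inherits(x, "harmonized_set")) x$pairs else x
  stopifnot(is.data.frame(p),
            all(c("beta_exposure", "se_exposure",
                  "beta_outcome", "se_outcome") %in% names(p)))
  p
}

#' Build a harmonized set directly from paired effect estimates
#'
#' Convenience constructor for simulation studies and for users holding
#' already-aligned per-variant effect pairs.
#'
#' @param pairs Data frame with `variant_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome` (optional `eaf_exposure`,
#'   `eaf_outcome`, `pval_exposure`, alleles).
#' @param exposure_name,outcome_name Trait labels.
#' @return A `harmonized_set` with all pairs marked `aligned`.
#' @export
harmonized_set <- function(pairs, exposure_name = "exposure",
                           outcome_name = "outcome") {
  stopifnot(all(c("variant_id", "beta_exposure", "se_exposure",
                  "beta_outcome", "se_outcome") %in% names(pairs)))
  stopifnot(!anyDuplicated(pairs$variant_id),
            all(pairs$se_exposure > 0), all(pairs$se_outcome > 0))
  if (!"status" %in% names(pairs)) pairs$status <- "aligned"
  rownames(pairs) <- NULL
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 pairs = pairs, drop_log = pairs[0, , drop = FALSE]),
            class = "harmonized_set")
}
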