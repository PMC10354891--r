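#' Configuration for a two-sample MR analysis
#'
#' Collects every tunable threshold and seed used by instrument selection,
#' harmonization, estimation, sensitivity diagnostics and grid screening.
#'
#' @param p_threshold Exposure p-value cut for candidate instruments; a
#'   variant is kept when `pval < p_threshold` (strict). Default `1e-5`,
#'   the relaxed cut used when few variants reach genome-wide significance.
#' @param clump_r2 LD pruning threshold: within the clumping window a
#'   retained pair must have r-squared below this value, so variants with
#'   `r2 >= clump_r2` relative to an index variant are removed.
#'   Default `0.001`.
#' @param clump_window_bp Half-width in base pairs of the clumping window
#'   around an index variant (a "10 Mb window" read as +/- 10 Mb).
#'   Default `1e7`.
#' @param proxy_r2 Minimum LD for proxy substitution; a proxy qualifies only
#'   with `r2 > proxy_r2` (strict). Default `0.8`.
#' @param f_threshold Minimum per-variant F statistic retained by the
#'   weak-instrument screen (`F >= f_threshold`). Default `10`.
#' @param confounder_p_threshold Annotation p-value below which a
#'   confounder-category association removes a variant. Default `5e-8`.
#' @param confounder_categories Annotation categories that trigger removal.
#' @param palindrome_window Effect-allele-frequency ambiguity interval for
#'   palindromic (A/T, C/G) variants; a palindrome whose frequency falls
#'   inside the open interval on either side is dropped. Default
#'   `c(0.42, 0.58)`.
#' @param palindrome_policy `"infer"` aligns unambiguous palindromes by
#'   frequency; `"drop"` discards all palindromes.
#' @param ivw_mode `"multiplicative_re"` (default) or `"fixed"`; the IVW
#'   variant used as the headline estimate and in the decision rules.
#' @param n_boot Parametric-bootstrap replicates for the weighted-median
#'   standard error. Default `1000`.
#' @param n_sim Simulation count for the MR-PRESSO global test.
#'   Default `2000`.
#' @param seed Master seed; all stochastic steps derive their streams from
#'   it (see [derive_seed()]).
#' @param alpha Nominal significance level. Default `0.05`.
#' @param family_size_override Optional integer replacing the realized grid
#'   size as the Bonferroni family size.
#' @return Object of class `mr_config` (a validated list).
#' @export
mr_config <- function(p_threshold = 1e-5,
                      clump_r2 = 0.001,
                      clump_window_bp = 1e7,
                      proxy_r2 = 0.8,
                      f_threshold = 10,
                      confounder_p_threshold = 5e-8,
                      confounder_categories = c("neurological", "psychiatric",
                                                "fluid intelligence",
                                                "obesity", "hypoxemia"),
                      palindrome_window = c(0.42, 0.58),
                      palindrome_policy = c("infer", "drop"),
                      ivw_mode = c("multiplicative_re", "fixed"),
                      n_boot = 1000,
                      n_sim = 2000,
                      seed = 1,
                      alpha = 0.05,
                      family_size_override = NULL) {
  palindrome_policy <- match.arg(palindrome_policy)
  ivw_mode <- match.arg(ivw_mode)
  stopifnot(p_threshold > 0, p_threshold <= 1,
            clump_r2 >= 0, clump_r2 < proxy_r2, proxy_r2 <= 1,
            clump_window_bp >= 0, f_threshold >= 0,
            confounder_p_threshold > 0, confounder_p_threshold <= 1,
            length(palindrome_window) == 2,
            palindrome_window[1] <= palindrome_window[2],
            n_boot >= 0, n_sim >= 1, alpha > 0, alpha < 1)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_bp = clump_window_bp, proxy_r2 = proxy_r2,
                 f_threshold = f_threshold,
                 confounder_p_threshold = confounder_p_threshold,
                 confounder_categories = confounder_categories,
                 palindrome_window = palindrome_window,
                 palindrome_policy = palindrome_policy,
                 ivw_mode = ivw_mode, n_boot = n_boot, n_sim = n_sim,
                 seed = as.integer(seed), alpha = alpha,
                 family_size_override = family_size_override),
            class = "mr_config")
}

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' Stable 31-bit string hash (polynomial rolling hash mod 2^31 - 1) of the
#' master seed and any number of key components. Used to give every
#' stochastic step, grid cell and replicate its own deterministic stream,
#' independent of execution order.
#'
#' @param seed Integer master seed.
#' @param ... Key components (coerced to character).
#' @return A single integer in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(as.integer(seed)), as.character(unlist(list(...)))),
               collapse = "\x1f")
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Filter variants by exposure p-value
#'
#' Keeps records with `pval < p_threshold` (strict inequality), preserving
#' input order.
#'
#' @param dataset A `summary_dataset` or records data frame.
#' @param p_threshold Significance cut.
#' @return Records data frame of the retained variants (possibly 0 rows).
#' @export
filter_by_pvalue <- function(dataset, p_threshold = 1e-5) {
  rec <- as_records(dataset)
  rec[rec$pval < p_threshold, , drop = FALSE]
}

#' Per-variant F statistic
#'
#' Single-variant approximation `F = (beta/se)^2`, the squared Wald
#' z-score; `F >= 10` is the conventional adequacy bound against weak
#' instrument bias.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return Numeric vector of F statistics.
#' @export
per_snp_f <- function(beta, se) {
  if (any(!(se > 0))) stop("se must be > 0")
  (beta / se)^2
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining variant with the smallest p-value
#' (variant_id as tie-break) as an index variant and removes all remaining
#' variants on the same chromosome within `clump_window_bp` of it whose
#' r-squared with the index is at least `clump_r2`. Variants absent from the
#' LD reference are treated as independent and reported in the
#' `not_in_ld` attribute.
#'
#' @param variants A `summary_dataset` or records data frame (needs
#'   `variant_id`, `chrom`, `pos`, `pval`).
#' @param ld_reference An `ld_reference`, or `NULL` (all independent).
#' @param clump_r2 Removal threshold (r2 >= clump_r2 removes).
#' @param clump_window_bp Window half-width in base pairs.
#' @return Character vector of retained (index) variant ids in selection
#'   order, with attribute `not_in_ld`.
#' @export
ld_clump <- function(variants, ld_reference = NULL, clump_r2 = 0.001,
                     clump_window_bp = 1e7) {
  rec <- as_records(variants)
  if (nrow(rec) == 0) return(character(0))
  ord <- order(rec$pval, rec$variant_id)
  rec <- rec[ord, , drop = FALSE]
  in_ld <- if (is.null(ld_reference)) rep(FALSE, nrow(rec))
           else rec$variant_id %in% ld_reference$variant_ids
  remaining <- seq_len(nrow(rec))
  kept <- integer(0)
  while (length(remaining) > 0) {
    idx <- remaining[1]
    kept <- c(kept, idx)
    remaining <- remaining[-1]
    if (length(remaining) == 0) break
    same_chr <- rec$chrom[remaining] == rec$chrom[idx]
    in_win <- abs(rec$pos[remaining] - rec$pos[idx]) <= clump_window_bp
    cand <- remaining[same_chr & in_win]
    if (length(cand) > 0) {
      r2 <- vapply(rec$variant_id[cand], function(v) {
        r2_between(ld_reference, rec$variant_id[idx], v)
      }, numeric(1))
      remaining <- setdiff(remaining, cand[r2 >= clump_r2])
    }
  }
  out <- rec$variant_id[kept]
  attr(out, "not_in_ld") <- rec$variant_id[!in_ld]
  out
}

#' Find a proxy variant for an instrument missing from the outcome dataset
#'
#' Returns the outcome-dataset variant with maximal r-squared to the missing
#' variant, provided `r2 > proxy_r2` (strict). Exact ties are broken by the
#' candidate's exposure p-value (ascending, when an exposure dataset is
#' supplied) and then lexicographic variant id.
#'
#' @param missing_variant Variant id absent from the outcome dataset.
#' @param outcome_dataset A `summary_dataset` (or records data frame) for
#'   the outcome trait.
#' @param ld_reference An `ld_reference` covering the missing variant.
#' @param proxy_r2 Strict lower bound on qualifying LD.
#' @param exposure_dataset Optional exposure `summary_dataset` used for the
#'   p-value tie-break (a proxy is only usable downstream if it also has an
#'   exposure record).
#' @return List with `variant_id` and `r2`, or `NULL` when no candidate
#'   qualifies.
#' @export
find_proxy <- function(missing_variant, outcome_dataset, ld_reference,
                       proxy_r2 = 0.8, exposure_dataset = NULL) {
  if (is.null(ld_reference) ||
      !missing_variant %in% ld_reference$variant_ids) return(NULL)
  out_ids <- as_records(outcome_dataset)$variant_id
  cand <- setdiff(intersect(out_ids, ld_reference$variant_ids),
                  missing_variant)
  if (length(cand) == 0) return(NULL)
  r2 <- ld_reference$r2[missing_variant, cand]
  qual <- r2 > proxy_r2
  if (!any(qual)) return(NULL)
  cand <- cand[qual]
  r2 <- r2[qual]
  best <- r2 == max(r2)
  cand <- cand[best]
  r2 <- r2[best]
  if (length(cand) > 1) {
    expo_p <- rep(Inf, length(cand))
    if (!is.null(exposure_dataset)) {
      erec <- as_records(exposure_dataset)
      m <- match(cand, erec$variant_id)
      expo_p[!is.na(m)] <- erec$pval[m[!is.na(m)]]
    }
    o <- order(expo_p, cand)
    cand <- cand[o]
    r2 <- r2[o]
  }
  list(variant_id = cand[1], r2 = unname(r2[1]))
}

#' Remove variants annotated to confounder categories
#'
#' A variant is removed if and only if it carries at least one annotation
#' whose category is in `categories` with `pval < p_threshold`.
#'
#' @param variant_ids Character vector of candidate instrument ids.
#' @param annotations Annotation data frame (`variant_id`, `trait`,
#'   `category`, `pval`) or `NULL` (nothing removed).
#' @param categories Categories that trigger removal.
#' @param p_threshold Annotation significance cut (strict `<`).
#' @return List with `kept` (ids, input order preserved) and `removal_log`
#'   (data frame of `variant_id`, `trait`, `category`, `pval`).
#' @export
confounder_filter <- function(variant_ids, annotations, categories,
                              p_threshold = 5e-8) {
  empty_log <- data.frame(variant_id = character(0), trait = character(0),
                          category = character(0), pval = numeric(0),
                          stringsAsFactors = FALSE)
  if (is.null(annotations) || nrow(annotations) == 0 ||
      length(categories) == 0) {
    return(list(kept = variant_ids, removal_log = empty_log))
  }
  hit <- annotations$variant_id %in% variant_ids &
    annotations$category %in% categories &
    annotations$pval < p_threshold
  log <- annotations[hit, c("variant_id", "trait", "category", "pval"),
                     drop = FALSE]
  rownames(log) <- NULL
  list(kept = variant_ids[!variant_ids %in% log$variant_id],
       removal_log = log)
}

#' Select genetic instruments for one exposure
#'
#' Applies, in order: the exposure p-value filter, greedy LD clumping, proxy
#' substitution for selected variants missing from the outcome dataset, the
#' F-statistic screen, and confounder pruning. Stage attrition is recorded
#' in an audit vector; an empty final set is a regular result
#' (`no_instruments = TRUE`), not an error.
#'
#' Proxy substitution replaces the missing variant by the proxy's own
#' records in both datasets (no effect imputation); a proxy therefore must
#' carry an exposure record too, and variants with no qualifying proxy are
#' dropped.
#'
#' @param exposure Exposure `summary_dataset`.
#' @param outcome Outcome `summary_dataset`.
#' @param ld_reference An `ld_reference` or `NULL`.
#' @param annotations Confounder annotation data frame or `NULL`.
#' @param config An [mr_config()].
#' @return Object of class `instrument_set`: `selected` (exposure records of
#'   the final instruments), `f_stats`, `audit` (named counts: `input`,
#'   `post_p_filter`, `post_clump`, `post_proxy`, `post_f`,
#'   `post_confounder`), `proxy_log`, `confounder_log`, `not_in_ld`,
#'   `trait_name`, `no_instruments`.
#' @export
select_instruments <- function(exposure, outcome, ld_reference = NULL,
                               annotations = NULL, config = mr_config()) {
  erec <- as_records(exposure)
  audit <- c(input = nrow(erec))

  cand <- filter_by_pvalue(erec, config$p_threshold)
  audit["post_p_filter"] <- nrow(cand)

  kept_ids <- ld_clump(cand, ld_reference, config$clump_r2,
                       config$clump_window_bp)
  not_in_ld <- attr(kept_ids, "not_in_ld")
  cand <- cand[match(kept_ids, cand$variant_id), , drop = FALSE]
  audit["post_clump"] <- nrow(cand)

  out_ids <- as_records(outcome)$variant_id
  proxy_log <- data.frame(variant_id = character(0), proxy = character(0),
                          r2 = numeric(0), stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    row <- cand[i, , drop = FALSE]
    if (row$variant_id %in% out_ids) {
      rows[[i]] <- row
    } else {
      px <- find_proxy(row$variant_id, outcome, ld_reference,
                       config$proxy_r2, exposure)
      if (!is.null(px) && px$variant_id %in% erec$variant_id) {
        proxy_log <- rbind(proxy_log,
                           data.frame(variant_id = row$variant_id,
                                      proxy = px$variant_id, r2 = px$r2,
                                      stringsAsFactors = FALSE))
        rows[[i]] <- erec[erec$variant_id == px$variant_id, , drop = FALSE]
      }
    }
  }
  cand <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(cand)) cand <- erec[0, , drop = FALSE]
  cand <- cand[!duplicated(cand$variant_id), , drop = FALSE]
  audit["post_proxy"] <- nrow(cand)

  f <- if (nrow(cand) > 0) per_snp_f(cand$beta, cand$se) else numeric(0)
  keep <- f >= config$f_threshold
  cand <- cand[keep, , drop = FALSE]
  f <- f[keep]
  audit["post_f"] <- nrow(cand)

  cf <- confounder_filter(cand$variant_id, annotations,
                          config$confounder_categories,
                          config$confounder_p_threshold)
  cand <- cand[cand$variant_id %in% cf$kept, , drop = FALSE]
  audit["post_confounder"] <- nrow(cand)

  f_stats <- if (nrow(cand) > 0) per_snp_f(cand$beta, cand$se) else numeric(0)
  names(f_stats) <- cand$variant_id
  rownames(cand) <- NULL
  structure(list(selected = cand, f_stats = f_stats, audit = audit,
                 proxy_log = proxy_log, confounder_log = cf$removal_log,
                 not_in_ld = not_in_ld,
                 trait_name = trait_name_of(exposure, "exposure"),
                 no_instruments = nrow(cand) == 0),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d instruments\n", x$trait_name,
              nrow(x$selected)))
  cat("  audit:", paste(names(x$audit), x$audit, sep = "=",
                        collapse = " "), "\n")
  invisible(x)
}
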