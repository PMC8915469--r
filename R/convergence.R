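resolve_matrix_filter <- function(matrix_filter) {
  if (is.null(matrix_filter)) return(matrix_levels())
  if (length(matrix_filter) == 1L && matrix_filter == "all") {
    return(matrix_levels())
  }
  if (length(matrix_filter) == 1L && matrix_filter == "rectal_only") {
    return(c("rectal", "meconium"))
  }
  bad <- setdiff(matrix_filter, matrix_levels())
  if (length(bad)) {
    stop("unknown matrix type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  matrix_filter
}

#' Within-family heterogeneity per time point
#'
#' For each (family, time point) cell, the heterogeneity is the
#' arithmetic mean of all pairwise distances among that family's
#' samples at that time ("mean diversity"). Cells with fewer than two
#' samples have undefined heterogeneity (`NA`) but are retained with
#' their sample count.
#'
#' @param d labelled distance matrix, e.g. from
#'   [phi_distance_matrix()]; its labels must cover all selected
#'   samples.
#' @param samples sample metadata frame.
#' @param matrix_filter `"all"` (default: every sample matrix),
#'   `"rectal_only"` (rectal swabs incl. meconium), or a character
#'   vector of matrix types.
#' @param include_dams keep dam samples in each family's set (default
#'   `TRUE`; the family pools dam and puppies).
#' @return data.frame with columns `family_id`, `time_point`,
#'   `n_samples`, `heterogeneity`.
#' @export
within_family_heterogeneity <- function(d, samples, matrix_filter = "all",
                                        include_dams = TRUE) {
  validate_sample_meta(samples)
  validate_distance_matrix(d)
  keep_matrix <- resolve_matrix_filter(matrix_filter)
  sel <- samples[samples$matrix %in% keep_matrix, , drop = FALSE]
  if (!include_dams) sel <- sel[sel$subject_role != "dam", , drop = FALSE]
  miss <- setdiff(sel$sample_id, rownames(d))
  if (length(miss)) {
    stop("distance matrix lacks sample(s): ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  fams <- sort(unique(samples$family_id))
  grid <- expand.grid(family_id = fams, time_point = tp_levels(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ids <- sel$sample_id[sel$family_id == grid$family_id[i] &
                           sel$time_point == grid$time_point[i]]
    n <- length(ids)
    het <- if (n >= 2L) {
      sub <- d[ids, ids, drop = FALSE]
      mean(sub[upper.tri(sub)])
    } else NA_real_
    data.frame(family_id = grid$family_id[i],
               time_point = grid$time_point[i],
               n_samples = n, heterogeneity = het,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  empty <- tapply(out$n_samples, out$family_id, sum) == 0L
  if (any(empty)) {
    warning("family with no samples at any time point under this filter: ",
            paste(names(empty)[empty], collapse = ", "), call. = FALSE)
  }
  out[order(out$family_id, match(out$time_point, tp_levels())), ]
}

#' Exact Wilcoxon rank-sum test by full enumeration
#'
#' Two-sample rank-sum test whose null distribution is obtained by
#' enumerating all `choose(n_a + n_b, n_a)` assignments of the observed
#' (mid-)ranks to group A, so ties are handled exactly (the null is
#' conditional on the observed tie pattern). The two-sided p doubles
#' the smaller tail, capped at 1. When the number of assignments
#' exceeds `exact_limit` the test falls back to the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param a,b numeric vectors (group A and B observations), each
#'   non-empty.
#' @param exact_limit enumeration cutoff on `choose(n_a + n_b, n_a)`
#'   (default 200000).
#' @return object of class `"ranksum_result"`: list with `statistic_W`
#'   (rank sum of group A, mid-ranks), `n_a`, `n_b`, `p_two_sided`,
#'   `method` (`"exact_enumeration"` or `"normal_approx"`).
#' @examples
#' ranksum_exact(1:3, 4:6)$p_two_sided  # 0.1
#' @export
ranksum_exact <- function(a, b, exact_limit = 200000) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b)))) {
    stop("groups must contain finite values only", call. = FALSE)
  }
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))                      # mid-ranks
  w_obs <- sum(r[seq_len(na)])
  eps <- 1e-9
  if (choose(n, na) <= exact_limit) {
    idx <- utils::combn(n, na)
    w_null <- colSums(matrix(r[idx], nrow = na))
    p_le <- mean(w_null <= w_obs + eps)
    p_ge <- mean(w_null >= w_obs - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact_enumeration"
  } else {
    mu <- na * (n + 1) / 2
    ties <- table(r)
    sigma2 <- na * nb / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z_num <- w_obs - mu
    z <- (z_num - sign(z_num) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(statistic_W = w_obs, n_a = na, n_b = nb,
                 p_two_sided = p, method = method),
            class = "ranksum_result")
}

#' @export
print.ranksum_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): W = %g, n = %d vs %d, p = %.6g\n",
              x$method, x$statistic_W, x$n_a, x$n_b, x$p_two_sided))
  invisible(x)
}

#' Compare each time point's heterogeneity against birth
#'
#' Pools the per-family heterogeneity values at each later time point
#' and compares them with the values at birth (T0) by the unpaired
#' exact Wilcoxon rank-sum test. Raw p-values are reported; an optional
#' Holm adjustment over the three comparisons can be switched on.
#'
#' @param het heterogeneity table from [within_family_heterogeneity()].
#' @param times time points to compare against T0 (default T2, T30,
#'   T60).
#' @param holm_adjust add a Holm-adjusted p column (default `FALSE`).
#' @return data.frame with one row per comparison: `comparison`,
#'   `time_point`, `W`, `n_a`, `n_b`, `p`, `method`; a comparison with
#'   fewer than two defined values in either group is flagged
#'   `not_testable` with `NA` p.
#' @export
compare_to_birth <- function(het, times = c("T2", "T30", "T60"),
                             holm_adjust = FALSE) {
  stopifnot(all(c("time_point", "heterogeneity") %in% names(het)))
  pick <- function(tp) {
    v <- het$heterogeneity[het$time_point == tp]
    v[!is.na(v)]
  }
  b0 <- pick("T0")
  rows <- lapply(times, function(tp) {
    v <- pick(tp)
    if (length(v) < 2L || length(b0) < 2L) {
      return(data.frame(comparison = paste0(tp, "_vs_T0"), time_point = tp,
                        W = NA_real_, n_a = length(v), n_b = length(b0),
                        p = NA_real_, method = "not_testable",
                        stringsAsFactors = FALSE))
    }
    rs <- ranksum_exact(v, b0)
    data.frame(comparison = paste0(tp, "_vs_T0"), time_point = tp,
               W = rs$statistic_W, n_a = rs$n_a, n_b = rs$n_b,
               p = rs$p_two_sided, method = rs$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (holm_adjust) out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}
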