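#' Summarize junction calls into editing-outcome statistics
#'
#' Computes category counts and the three normalization conventions used for
#' reporting:
#' * **total events** = indels + large deletions + translocations + uncut +
#'   AAV integrations (ambiguous molecules are excluded everywhere);
#' * **editing events** for editing efficiency and translocation rates =
#'   indels + large deletions + translocations, *excluding* AAV
#'   integrations;
#' * **editing events** for AAV rates = indels + large deletions +
#'   translocations + AAV integrations.
#'
#' @param calls Molecule-level junction-call tibble (from
#'   [call_junctions()]), or a named count vector/list with entries among
#'   `indel`, `large_deletion`, `offtarget_translocation`,
#'   `general_translocation`, `aav_integration`, `uncut`, `ambiguous`.
#' @param large_del_in_edited Count large deletions inside editing events
#'   (default `TRUE`; recorded in the output metadata).
#' @return An `editing_summary` object; see [glance.editing_summary()] for
#'   the percentage fields. Percentages are `NA` when their denominator is
#'   zero.
#' @export
#' @examples
#' summarize_calls(c(indel = 70, offtarget_translocation = 2,
#'                   general_translocation = 4, aav_integration = 24,
#'                   uncut = 900))
summarize_calls <- function(calls, large_del_in_edited = TRUE) {
  if (is.data.frame(calls)) {
    counts <- table(factor(calls$class, levels = JUNCTION_CLASSES))
    counts <- setNames(as.integer(counts), names(counts))
  } else {
    counts <- setNames(rep(0L, length(JUNCTION_CLASSES)), JUNCTION_CLASSES)
    given <- unlist(calls)
    bad <- setdiff(names(given), JUNCTION_CLASSES)
    if (length(bad)) stop("unknown classes: ", paste(bad, collapse = ", "))
    counts[names(given)] <- as.integer(given)
  }
  n_indel <- counts[["indel"]]
  n_large_del <- counts[["large_deletion"]]
  n_ot_tx <- counts[["offtarget_translocation"]]
  n_gen_tx <- counts[["general_translocation"]]
  n_aav <- counts[["aav_integration"]]
  n_uncut <- counts[["uncut"]]
  n_ambiguous <- counts[["ambiguous"]]

  ld_edit <- if (large_del_in_edited) n_large_del else 0L
  edited <- n_indel + ld_edit + n_ot_tx + n_gen_tx       # AAV excluded
  edited_aav <- edited + n_aav                            # AAV included
  total <- n_indel + n_large_del + n_ot_tx + n_gen_tx + n_uncut + n_aav

  structure(
    list(
      counts = tibble::tibble(
        class = JUNCTION_CLASSES,
        n = as.integer(counts[JUNCTION_CLASSES])
      ),
      total_events = total,
      editing_efficiency = pct(edited, total),
      ot_tx_pct_of_edited = pct(n_ot_tx, edited),
      gen_tx_pct_of_edited = pct(n_gen_tx, edited),
      large_del_pct_of_edited = pct(n_large_del, edited),
      aav_pct_of_total = pct(n_aav, total),
      aav_pct_of_edited = pct(n_aav, edited_aav),
      n_ambiguous = n_ambiguous,
      large_del_in_edited = large_del_in_edited
    ),
    class = "editing_summary"
  )
}

#' @export
print.editing_summary <- function(x, ...) {
  cat("<editing_summary> ", x$total_events, " total events (",
      x$n_ambiguous, " ambiguous excluded)\n", sep = "")
  nz <- x$counts[x$counts$n > 0, ]
  if (nrow(nz)) {
    cat(paste0("  ", format(nz$class, width = 24), nz$n, collapse = "\n"), "\n")
  }
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f%%", v))
  cat("  editing efficiency      ", fmt(x$editing_efficiency), "\n",
      "  off-target tx / edited  ", fmt(x$ot_tx_pct_of_edited), "\n",
      "  general tx / edited     ", fmt(x$gen_tx_pct_of_edited), "\n",
      "  AAV / total             ", fmt(x$aav_pct_of_total), "\n",
      "  AAV / edited(+AAV)      ", fmt(x$aav_pct_of_edited), "\n", sep = "")
  invisible(x)
}

#' Tidy per-class counts of an editing summary
#'
#' @param x An `editing_summary`.
#' @param ... Unused.
#' @return Tibble `class`, `n`, `pct_of_total`.
#' @method tidy editing_summary
#' @export
tidy.editing_summary <- function(x, ...) {
  dplyr::mutate(
    x$counts,
    pct_of_total = dplyr::if_else(
      class == "ambiguous", NA_real_,
      purrr::map_dbl(n, pct, den = x$total_events)
    )
  )
}

#' One-row percentage summary of an editing summary
#'
#' @param x An `editing_summary`.
#' @param ... Unused.
#' @return One-row tibble with the total-event count and the normalized
#'   percentages (two-decimal reporting is applied by `print()`; values here
#'   are unrounded).
#' @method glance editing_summary
#' @export
glance.editing_summary <- function(x, ...) {
  tibble::tibble(
    total_events = x$total_events,
    editing_efficiency = x$editing_efficiency,
    ot_tx_pct_of_edited = x$ot_tx_pct_of_edited,
    gen_tx_pct_of_edited = x$gen_tx_pct_of_edited,
    large_del_pct_of_edited = x$large_del_pct_of_edited,
    aav_pct_of_total = x$aav_pct_of_total,
    aav_pct_of_edited = x$aav_pct_of_edited,
    n_ambiguous = x$n_ambiguous
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Fold change between two percentages
#'
#' @param a,b Percentages (or rates); the ratio `a / b` is reported to one
#'   decimal place.
#' @param pseudocount Optional value added to both terms when `b` is zero,
#'   turning the result into a floor estimate; without it a zero denominator
#'   yields `NA`.
#' @return Numeric fold change (vectorised).
#' @export
#' @examples
#' fold_change(0.56, 0.13) # 4.3
#' fold_change(0.1, 0.003) # 33.3
fold_change <- function(a, b, pseudocount = NULL) {
  if (!is.null(pseudocount)) {
    a <- a + pseudocount
    b <- b + pseudocount
  }
  out <- ifelse(b > 0, round(a / b, 1L), NA_real_)
  if (any(is.na(out) & !is.na(a))) {
    message("zero denominator: fold change undefined (supply a pseudocount ",
            "for a floor estimate)")
  }
  out
}

#' Two-sided Welch t-test between two groups
#'
#' Welch's unequal-variance form of the two-tailed Student's t-test, with
#' group means and standard deviations as reported in figure legends.
#' Degenerate zero-variance groups are handled explicitly: identical groups
#' give `t = 0`, `p = 1`.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 2).
#' @return One-row tibble: `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`,
#'   `statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs n >= 2")
  }
  na <- length(values_a); nb <- length(values_b)
  ma <- mean(values_a); mb <- mean(values_b)
  va <- var(values_a); vb <- var(values_b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    t <- if (ma == mb) 0 else sign(ma - mb) * Inf
    df <- NA_real_
    p <- if (ma == mb) 1 else 0
  } else {
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * pt(-abs(t), df)
  }
  tibble::tibble(
    mean_a = ma, sd_a = sqrt(va), n_a = na,
    mean_b = mb, sd_b = sqrt(vb), n_b = nb,
    statistic = t, df = df, p_value = p
  )
}

#' Vector-side junction profile and ITR fraction
#'
#' Histogram of AAV-side breakpoint coordinates over the vector, with the
#' fraction of junctions falling inside the annotated ITR intervals.
#'
#' @param calls Junction-call tibble; only `aav_integration` molecules are
#'   used.
#' @param vector A [build_aav_vector()] object.
#' @param binwidth Histogram bin width in bp (default 50).
#' @return A `vector_profile`: list with `histogram` (tibble `bin_start`,
#'   `bin_end`, `count`), `itr_fraction` (`NA` when there are no AAV calls),
#'   and `n_junctions`.
#' @export
vector_junction_profile <- function(calls, vector, binwidth = 50L) {
  stopifnot(inherits(vector, "vector_map"))
  aav <- calls[!is.na(calls$class) & calls$class == "aav_integration" &
                 !is.na(calls$prey_pos), , drop = FALSE]
  vlen <- nchar(vector$sequence)
  breaks <- seq(0L, vlen + binwidth, by = binwidth)
  pos <- aav$prey_pos
  hist <- tibble::tibble(
    bin_start = head(breaks, -1L),
    bin_end = pmin(breaks[-1L], vlen)
  )
  hist <- hist[hist$bin_start < vlen, , drop = FALSE]
  hist$count <- vapply(seq_len(nrow(hist)), function(i) {
    sum(pos >= hist$bin_start[i] & pos < hist$bin_end[i])
  }, integer(1))
  structure(
    list(
      histogram = hist,
      itr_fraction = if (nrow(aav) > 0L) mean(in_itr(pos, vector)) else NA_real_,
      n_junctions = nrow(aav),
      vector_length = vlen,
      itr_intervals = vector$itr_intervals
    ),
    class = "vector_profile"
  )
}

#' @export
print.vector_profile <- function(x, ...) {
  cat("<vector_profile> ", x$n_junctions, " AAV junctions; ITR fraction ",
      ifelse(is.na(x$itr_fraction), "NA",
             sprintf("%.3f", x$itr_fraction)), "\n", sep = "")
  invisible(x)
}
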