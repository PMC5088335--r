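#' Age/sex reference statistics for anthropometric indices
#'
#' Weighted means and standard deviations of each index within sex and age
#' bins, used to transform raw index values to age- and sex-specific z
#' scores.  Bins tile \code{age_range} at \code{age_bin_width} years with a
#' terminal open bin.
#'
#' @param panel Index panel from [compute_index_panel()] (needs columns
#'   \code{age_years}, \code{female}, \code{sample_weight} and the requested
#'   indices).
#' @param index_names Indices to tabulate (default height, BMI, ABSI, HI).
#' @param age_bin_width Bin width in years (default 5).
#' @param use_sample_weights Weight by \code{sample_weight} (default TRUE).
#' @param sd_denom \code{"population"} (denominator = total weight; default,
#'   since the table describes a population) or \code{"sample"} (total weight
#'   minus one).
#' @param age_range Ages covered by regular bins (default 18 to 85); the last
#'   bin is open-ended.
#'
#' @return A \code{"reference_stats"} data frame with columns
#'   \code{index_name}, \code{sex}, \code{age_lo}, \code{age_hi}, \code{mean},
#'   \code{sd}, \code{effective_n}.
#' @export
estimate_reference_stats <- function(panel,
                                     index_names = c("height", "bmi",
                                                     "absi", "hi"),
                                     age_bin_width = 5,
                                     use_sample_weights = TRUE,
                                     sd_denom = c("population", "sample"),
                                     age_range = c(18, 85)) {
  sd_denom <- match.arg(sd_denom)
  if (nrow(panel) == 0L) stop("insufficient data: empty cohort")
  missing_idx <- setdiff(index_names, names(panel))
  if (length(missing_idx))
    stop("unknown index: ", paste(missing_idx, collapse = ", "))
  edges <- c(seq(age_range[1], age_range[2], by = age_bin_width), Inf)
  w_all <- if (use_sample_weights) panel$sample_weight else
    rep(1, nrow(panel))
  bin <- findInterval(panel$age_years, edges)
  if (any(bin == 0)) stop("age below reference range")

  rows <- list()
  for (idx in index_names) {
    for (sex in 0:1) {
      for (b in seq_len(length(edges) - 1L)) {
        sel <- panel$female == sex & bin == b
        w <- w_all[sel]
        v <- panel[[idx]][sel]
        if (length(v) >= 2L && sum(w) > 0) {
          m <- sum(w * v) / sum(w)
          denom <- if (sd_denom == "population") sum(w) else sum(w) - 1
          s <- sqrt(sum(w * (v - m)^2) / denom)
          en <- sum(w)^2 / sum(w^2)
        } else {
          m <- NA_real_; s <- NA_real_; en <- 0
        }
        rows[[length(rows) + 1L]] <- data.frame(
          index_name = idx, sex = sex, age_lo = edges[b],
          age_hi = edges[b + 1L], mean = m, sd = s, effective_n = en)
      }
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("reference_stats", "data.frame"),
            age_bin_edges = edges, sd_denom = sd_denom)
}

#' @keywords internal
lookup_cells <- function(stats, index_name, female, age, clamp_age = FALSE) {
  edges <- attr(stats, "age_bin_edges")
  b <- findInterval(age, edges)
  if (!clamp_age && any(b == 0))
    stop("age outside the reference range (set clamp_age = TRUE to clamp)")
  b[b == 0] <- 1L
  sub <- stats[stats$index_name == index_name, , drop = FALSE]
  if (nrow(sub) == 0L) stop("unknown index: ", index_name)
  out_mean <- rep(NA_real_, length(age))
  out_sd <- rep(NA_real_, length(age))
  for (sex in unique(female)) {
    s <- sub[sub$sex == sex, , drop = FALSE]
    s <- s[order(s$age_lo), , drop = FALSE]
    populated <- which(is.finite(s$mean) & s$effective_n > 0)
    if (!length(populated))
      stop("no populated reference cells for index '", index_name,
           "', sex ", sex)
    sel <- female == sex
    bb <- b[sel]
    if (clamp_age) {   # snap out-of-range or unpopulated bins to the
      off <- !(bb %in% populated)      # nearest populated one
      if (any(off))
        bb[off] <- vapply(bb[off], function(x)
          populated[which.min(abs(populated - x))], integer(1))
    }
    if (any(!(bb %in% populated)))
      stop("empty reference cell encountered for index '", index_name, "'")
    if (any(s$sd[bb] <= 0))
      stop("degenerate reference cell (sd = 0) for index '", index_name, "'")
    out_mean[sel] <- s$mean[bb]
    out_sd[sel] <- s$sd[bb]
  }
  data.frame(mean = out_mean, sd = out_sd)
}

#' Z-score a cohort against reference statistics
#'
#' Transforms each requested index to its age- and sex-specific z score,
#' \code{(value - cell mean) / cell sd}.
#'
#' @param panel Index panel (see [compute_index_panel()]).
#' @param stats \code{"reference_stats"} table.
#' @param index_names Indices to transform (default: those present in
#'   \code{stats}).
#' @param clamp_age Snap ages falling in an out-of-range or unpopulated bin
#'   to the nearest populated bin instead of erroring (needed when scoring an
#'   older external cohort, or small cohorts with sparse bins).
#' @return \code{panel} with added columns \code{z_<index>}.
#' @export
zscore_cohort <- function(panel, stats,
                          index_names = unique(stats$index_name),
                          clamp_age = FALSE) {
  for (idx in index_names) {
    cell <- lookup_cells(stats, idx, panel$female, panel$age_years,
                         clamp_age = clamp_age)
    panel[[paste0("z_", idx)]] <- (panel[[idx]] - cell$mean) / cell$sd
  }
  panel
}

#' Z-score a single subject's index values
#'
#' @param values Named numeric vector of index values (names as in the
#'   reference table, e.g. \code{c(height = 170, bmi = 27, ...)}).
#' @param age Age in years.
#' @param female 1 for female, 0 for male.
#' @inheritParams zscore_cohort
#' @return Named numeric vector of z scores.
#' @export
zscore_transform <- function(values, age, female, stats, clamp_age = FALSE) {
  out <- vapply(names(values), function(idx) {
    cell <- lookup_cells(stats, idx, female, age, clamp_age = clamp_age)
    (values[[idx]] - cell$mean) / cell$sd
  }, numeric(1))
  names(out) <- names(values)
  out
}

#' Convert z scores to population percentiles
#'
#' The \code{"normal"} method returns \code{100 * pnorm(z)}; the
#' \code{"empirical"} method returns the weighted fraction of a reference
#' cohort's z scores lying below \code{z}, in percent.
#'
#' @param z Numeric vector of z scores.
#' @param method \code{"normal"} (default) or \code{"empirical"}.
#' @param reference_z Reference cohort z scores (empirical method only).
#' @param reference_weights Optional weights for \code{reference_z}.
#' @return Percentiles in (0, 100).
#' @export
z_to_percentile <- function(z, method = c("normal", "empirical"),
                            reference_z = NULL, reference_weights = NULL) {
  method <- match.arg(method)
  stopifnot(all(is.finite(z)))
  if (method == "normal") return(100 * stats::pnorm(z))
  if (is.null(reference_z))
    stop("empirical method requires reference_z")
  w <- reference_weights %||% rep(1, length(reference_z))
  vapply(z, function(q) 100 * sum(w[reference_z < q]) / sum(w), numeric(1))
}

#' Weighted Pearson correlation matrix of indices
#'
#' Correlations of the raw index values, or of their age/sex z scores,
#' across a cohort.  A constant column yields \code{NA} (undefined), never 0.
#'
#' @param panel Index panel; when \code{on_zscores = TRUE} the corresponding
#'   \code{z_<index>} columns must be present (see [zscore_cohort()]).
#' @param index_names Indices to correlate.
#' @param on_zscores Correlate z scores instead of raw values.
#' @param use_sample_weights Weight by \code{sample_weight}.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(panel,
                               index_names = c("height", "weight_kg", "bmi",
                                               "waist_cm", "hip_cm", "absi",
                                               "whr", "hi"),
                               on_zscores = FALSE,
                               use_sample_weights = TRUE) {
  if (nrow(panel) < 3L) stop("insufficient data: need at least 3 records")
  cols <- if (on_zscores) paste0("z_", index_names) else index_names
  missing_idx <- setdiff(cols, names(panel))
  if (length(missing_idx))
    stop("unknown index: ", paste(missing_idx, collapse = ", "))
  X <- as.matrix(panel[, cols, drop = FALSE])
  w <- if (use_sample_weights) panel$sample_weight else rep(1, nrow(panel))
  w <- w / sum(w)
  mu <- colSums(w * X)
  Xc <- sweep(X, 2, mu)
  cv <- crossprod(Xc * sqrt(w), Xc * sqrt(w))
  s <- sqrt(diag(cv))
  r <- cv / tcrossprod(s)
  r[, s == 0] <- NA_real_
  r[s == 0, ] <- NA_real_
  diag(r) <- 1
  dimnames(r) <- list(index_names, index_names)
  r
}

#' Combined raw/z-score correlation table
#'
#' Upper-right triangle: correlations of the raw values; lower-left triangle:
#' correlations of the age/sex z scores (the conventional presentation of
#' anthropometric correlation tables).
#'
#' @inheritParams correlation_matrix
#' @return Square matrix with mixed triangles.
#' @export
correlation_table <- function(panel, index_names, use_sample_weights = TRUE) {
  raw <- correlation_matrix(panel, index_names, on_zscores = FALSE,
                            use_sample_weights = use_sample_weights)
  zz <- correlation_matrix(panel, index_names, on_zscores = TRUE,
                           use_sample_weights = use_sample_weights)
  out <- raw
  out[lower.tri(out)] <- zz[lower.tri(zz)]
  out
}

#' Read/write reference statistics as CSV
#'
#' One row per (index, sex, age bin) cell, mirroring a published reference
#' table; round-trips losslessly.
#'
#' @param stats \code{"reference_stats"} table.
#' @param path File path.
#' @return \code{read_reference_stats} returns the restored table.
#' @export
write_reference_stats <- function(stats, path) {
  stopifnot(inherits(stats, "reference_stats"))
  utils::write.csv(as.data.frame(stats), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_stats
#' @export
read_reference_stats <- function(path) {
  df <- utils::read.csv(path)
  edges <- sort(unique(c(df$age_lo, df$age_hi)))
  structure(df, class = c("reference_stats", "data.frame"),
            age_bin_edges = edges, sd_denom = "unknown")
}
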