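#' Congener table I/O
#'
#' Long-form measured (or simulated) sampler masses, one row per
#' (experiment, day, replicate, group, matrix, peak). Columns are exactly
#' `experiment_id,day,replicate,group,matrix,peak_id,mass_ng`; mass is ng
#' per PUF or ng per cm fiber (SPME). Validation enforces non-negative
#' masses, the allowed factor levels, and uniqueness of the key.
#'
#' @param path CSV path
#' @return a validated data.frame
#' @export
read_congener_table <- function(path) {
  validate_congener_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_congener_table
#' @param table a congener-table data.frame
#' @export
write_congener_table <- function(table, path) {
  validate_congener_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.table_cols <- c("experiment_id", "day", "replicate", "group", "matrix",
                 "peak_id", "mass_ng")

#' @rdname read_congener_table
#' @export
validate_congener_table <- function(table) {
  missing <- setdiff(.table_cols, names(table))
  stop_if(length(missing) > 0, "congener table missing column(s): ",
          paste(missing, collapse = ", "))
  stop_if(any(table$mass_ng < 0), "congener table has negative masses")
  stop_if(!all(table$group %in% c("control", "treatment")),
          "group must be 'control' or 'treatment'")
  stop_if(!all(table$matrix %in% c("PUF", "SPME")),
          "matrix must be 'PUF' or 'SPME'")
  key <- do.call(paste, c(table[c("experiment_id", "day", "replicate",
                                  "group", "matrix", "peak_id")], sep = "\r"))
  stop_if(anyDuplicated(key) > 0,
          "duplicate (experiment, day, replicate, group, matrix, peak) rows")
  table
}

#' Limit of quantification from laboratory blanks
#'
#' LOQ per peak = mean(blanks) + 1.96 * sd(blanks), computed from the
#' laboratory blank sets run alongside the samples (typically n = 19 for
#' PUF and n = 3 for SPME). A `sqrt(n)` variant (standard error of the
#' blank mean instead of the blank SD) is available behind `se_of_mean`
#' for sensitivity checks; the per-sample reporting limit (default) is the
#' canonical form.
#'
#' @param blanks a [blank_set()]
#' @param se_of_mean if `TRUE`, divide the SD term by sqrt(n)
#' @return named numeric vector of per-peak LOQs (ng, same basis as the
#'   blank masses)
#' @export
compute_loq <- function(blanks, se_of_mean = FALSE) {
  stop_if(!inherits(blanks, "blank_set"), "blanks must be a blank_set")
  vapply(blanks$masses, function(m) {
    stop_if(length(m) < 2, "need >= 2 blanks per peak for an LOQ")
    s <- stats::sd(m)
    if (se_of_mean) s <- s / sqrt(length(m))
    mean(m) + 1.96 * s
  }, numeric(1))
}

#' Laboratory blank set
#'
#' @param matrix `"PUF"` or `"SPME"`
#' @param masses named list (by peak_id) of blank mass vectors, ng
#' @return an object of class `blank_set`
#' @export
blank_set <- function(matrix = c("PUF", "SPME"), masses) {
  matrix <- match.arg(matrix)
  stop_if(!is.list(masses) || is.null(names(masses)),
          "masses must be a named list of numeric vectors")
  for (m in masses) check_num(m, "blank masses", 0)
  structure(list(matrix = matrix, masses = masses,
                 n = vapply(masses, length, integer(1))),
            class = "blank_set")
}

#' Censor masses below the limit of quantification
#'
#' Replaces any mass strictly below its peak's LOQ with zero; masses equal
#' to or above the LOQ pass through unchanged. Idempotent.
#'
#' @param table a congener table
#' @param loq named per-peak LOQ vector (see [compute_loq()]); must cover
#'   every peak in the table
#' @return the censored table
#' @export
censor_below_loq <- function(table, loq) {
  validate_congener_table(table)
  missing <- setdiff(unique(table$peak_id), names(loq))
  stop_if(length(missing) > 0, "no LOQ for peak(s): ",
          paste(missing, collapse = ", "))
  below <- table$mass_ng < loq[table$peak_id]
  table$mass_ng[below] <- 0
  table
}

#' Correct congener masses for surrogate recovery
#'
#' Divides each peak's mass by the surrogate recovery of its homologue
#' group (each surrogate corrects the congeners sharing its chlorine
#' count). Errors if any homologue present in the table lacks a recovery
#' or has a non-positive one.
#'
#' @param table a congener table
#' @param recoveries a data.frame with columns `homologue` (integer
#'   chlorine count) and `recovery` (fraction in (0, 1.5]); see
#'   [generate_recoveries()]
#' @param congeners named list of [congener()] objects resolving peak ids
#'   to homologues
#' @return the corrected table
#' @export
surrogate_correct <- function(table, recoveries, congeners) {
  validate_congener_table(table)
  stop_if(any(recoveries$recovery <= 0), "recovery must be > 0")
  unknown <- setdiff(unique(table$peak_id), names(congeners))
  stop_if(length(unknown) > 0, "unknown peak(s): ", paste(unknown, collapse = ", "))
  hom <- vapply(congeners[table$peak_id], `[[`, integer(1), "homologue")
  rec <- recoveries$recovery[match(hom, recoveries$homologue)]
  stop_if(anyNA(rec), "missing recovery for homologue(s): ",
          paste(sort(unique(hom[is.na(rec)])), collapse = ", "))
  table$mass_ng <- table$mass_ng / rec
  table
}

#' Per-sample aggregate sums
#'
#' Collapses a congener table to per-sample totals: total PCBs, LC-PCBs
#' (peaks with three or fewer chlorines) and per-homologue sums.
#'
#' @param table a congener table
#' @param congeners named list of [congener()] objects covering every peak
#' @return a data.frame keyed by (experiment_id, day, replicate, group,
#'   matrix) with columns `total`, `lc`, and `hom_<k>` for each homologue
#'   present
#' @export
aggregate_sums <- function(table, congeners) {
  validate_congener_table(table)
  unknown <- setdiff(unique(table$peak_id), names(congeners))
  stop_if(length(unknown) > 0, "unknown peak(s): ", paste(unknown, collapse = ", "))
  ncl <- vapply(congeners[table$peak_id], `[[`, integer(1), "n_cl")
  key_cols <- c("experiment_id", "day", "replicate", "group", "matrix")
  tt <- table
  tt$.lc <- ifelse(ncl <= 3L, tt$mass_ng, 0)
  tt$.hom <- ncl
  out <- stats::aggregate(cbind(total = mass_ng, lc = .lc) ~
                            experiment_id + day + replicate + group + matrix,
                          data = tt, FUN = sum)
  for (h in sort(unique(ncl))) {
    tt$.mh <- ifelse(tt$.hom == h, tt$mass_ng, 0)
    hh <- stats::aggregate(.mh ~ experiment_id + day + replicate + group + matrix,
                           data = tt, FUN = sum)
    out[[paste0("hom_", h)]] <- hh$.mh[match(
      do.call(paste, c(out[key_cols], sep = "\r")),
      do.call(paste, c(hh[key_cols], sep = "\r")))]
  }
  out[order(out$group, out$matrix, out$day, out$replicate), ]
}

#' Signed percent difference between control and treatment means
#'
#' (control - treatment) / control * 100: positive values are decreases in
#' the treatment relative to the control, the convention used when
#' reporting, e.g., "54% fewer total PCBs". Values are conventionally
#' rounded to the nearest integer when reported.
#'
#' @param control_mean control group mean, must be > 0
#' @param treatment_mean treatment group mean, >= 0
#' @return signed percent difference (not rounded)
#' @examples
#' round(percent_difference(3980, 1840))  # 54
#' @export
percent_difference <- function(control_mean, treatment_mean) {
  stop_if(any(control_mean <= 0), "control_mean must be > 0")
  check_num(treatment_mean, "treatment_mean", 0)
  (control_mean - treatment_mean) / control_mean * 100
}

#' Treatment-vs-control comparison at one time point
#'
#' Compares an aggregate (total, LC, or a single peak) between groups at
#' one sampling day: masses are log10(x + eps) transformed (eps = half the
#' smallest positive mass in the comparison set, guarding censored zeros)
#' and tested with a paired two-tailed t-test on replicate-index pairs
#' (the default, mirroring the stated analysis on sacrificial triplicates)
#' or a two-sample Welch t-test. Significance at p < 0.05.
#'
#' @param table a congener table
#' @param day sampling day to compare
#' @param matrix `"PUF"` or `"SPME"`
#' @param congeners named list of [congener()] objects
#' @param aggregate `"total"`, `"lc"`, or a peak id
#' @param pairing `"paired"` or `"welch"`
#' @param eps log offset; `NULL` for the default rule
#' @return an object of class `group_comparison`: day, aggregate, per-group
#'   means and SDs (ng scale), percent difference, t statistic, p value,
#'   `significant` flag, and flags for degenerate cases (`zero_variance`,
#'   `censor_dominated` when half or more of the masses are zero)
#' @export
compare_time_point <- function(table, day, matrix, congeners,
                               aggregate = "total",
                               pairing = c("paired", "welch"), eps = NULL) {
  pairing <- match.arg(pairing)
  validate_congener_table(table)
  d <- table[table$day == day & table$matrix == matrix, , drop = FALSE]
  stop_if(nrow(d) == 0, sprintf("no rows at day %s for matrix %s", day, matrix))
  if (aggregate %in% c("total", "lc")) {
    agg <- aggregate_sums(d, congeners)
    val_col <- aggregate
  } else {
    stop_if(!aggregate %in% d$peak_id, "unknown aggregate: ", aggregate)
    agg <- d[d$peak_id == aggregate, c("experiment_id", "day", "replicate",
                                       "group", "matrix", "mass_ng")]
    val_col <- "mass_ng"
  }
  ctl <- agg[agg$group == "control", ]
  trt <- agg[agg$group == "treatment", ]
  stop_if(nrow(ctl) == 0 || nrow(trt) == 0, "need both groups at this day")
  ctl <- ctl[order(ctl$replicate), ]; trt <- trt[order(trt$replicate), ]
  x <- ctl[[val_col]]; y <- trt[[val_col]]
  stop_if(pairing == "paired" && length(x) != length(y),
          "paired comparison needs equal replicate counts")
  all_mass <- c(x, y)
  if (is.null(eps)) {
    pos <- all_mass[all_mass > 0]
    eps <- if (length(pos)) min(pos) / 2 else 1
  }
  lx <- log10(x + eps); ly <- log10(y + eps)
  zero_var <- if (pairing == "paired") stats::sd(lx - ly) == 0
              else (stats::sd(lx) == 0 && stats::sd(ly) == 0)
  if (zero_var) {
    tstat <- NA_real_; pval <- NA_real_
  } else if (pairing == "paired") {
    tt <- stats::t.test(lx, ly, paired = TRUE)
    tstat <- unname(tt$statistic); pval <- tt$p.value
  } else {
    tt <- stats::t.test(lx, ly, var.equal = FALSE)
    tstat <- unname(tt$statistic); pval <- tt$p.value
  }
  structure(list(day = day, matrix = matrix, aggregate = aggregate,
                 control_mean = mean(x), control_sd = stats::sd(x),
                 treatment_mean = mean(y), treatment_sd = stats::sd(y),
                 percent_difference = if (mean(x) > 0)
                   percent_difference(mean(x), mean(y)) else NA_real_,
                 t = tstat, p_value = pval,
                 significant = isTRUE(pval < 0.05),
                 pairing = pairing, eps = eps, n = c(length(x), length(y)),
                 zero_variance = zero_var,
                 censor_dominated = mean(all_mass == 0) >= 0.5),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> day %s, %s, %s (%s t-test)\n",
              x$day, x$matrix, x$aggregate, x$pairing))
  cat(sprintf("  control %.4g +/- %.3g | treatment %.4g +/- %.3g\n",
              x$control_mean, x$control_sd, x$treatment_mean, x$treatment_sd))
  cat(sprintf("  %% difference: %s%%  t = %.3g, p = %.4g%s%s\n",
              if (is.na(x$percent_difference)) "NA"
              else sprintf("%.0f", x$percent_difference),
              x$t, x$p_value,
              if (x$significant) " *" else "",
              if (x$censor_dominated) "  [censor-dominated]" else ""))
  invisible(x)
}

#' Run the canonical reduction pipeline
#'
#' Applies the QA reduction in its canonical order — censor below LOQ,
#' then surrogate-correct, then aggregate — and returns per-sample sums.
#' The order matters (correcting first would inflate masses past their
#' LOQs), so it is fixed here and pinned by a regression test.
#'
#' @param table a raw congener table
#' @param loq per-peak LOQ vector
#' @param recoveries surrogate recovery data.frame
#' @param congeners named list of [congener()] objects
#' @return per-sample aggregate sums (see [aggregate_sums()])
#' @export
reduce_measurements <- function(table, loq, recoveries, congeners) {
  table <- censor_below_loq(table, loq)
  table <- surrogate_correct(table, recoveries, congeners)
  aggregate_sums(table, congeners)
}
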