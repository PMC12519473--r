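#' PCB congener registry
#'
#' A congener record describes one PCB congener or one coeluting
#' chromatographic peak: its chlorine count, homologue group, and the
#' partitioning constants every transport calculation consumes. Coeluting
#' peaks (e.g. "PCB20+28") are treated as a single congener and must be
#' homologue-pure, because surrogate-recovery correction is applied per
#' homologue group.
#'
#' @param peak_id character label, e.g. "PCB4" or "PCB20+28"
#' @param n_cl integer chlorine count, 1-10
#' @param log_kow log10 octanol-water partition coefficient (dimensionless)
#' @param k_h dimensionless Henry's law constant, air/water concentration
#'   ratio; must be > 0
#' @param k_d sediment-water distribution coefficient, L/kg; must be >= 0
#' @param mw molar mass, g/mol
#' @param homologue integer homologue group; defaults to `n_cl` and must
#'   equal it (coeluting members share a homologue)
#' @return an object of class `congener` (a named list)
#' @examples
#' pcb4 <- congener("PCB4", n_cl = 2, log_kow = 4.65, k_h = 0.012,
#'                  k_d = 2500, mw = 223.1)
#' is_lc(pcb4)
#' @export
congener <- function(peak_id, n_cl, log_kow, k_h, k_d, mw,
                     homologue = n_cl) {
  stop_if(!is.character(peak_id) || length(peak_id) != 1L || !nzchar(peak_id),
          "peak_id must be a non-empty string")
  n_cl <- as.integer(n_cl)
  check_num(n_cl, "n_cl", 1, 10)
  check_num(log_kow, "log_kow")
  check_num(k_h, "k_h", lower = 0, allow_zero_lower = FALSE)
  check_num(k_d, "k_d", lower = 0)
  check_num(mw, "mw", lower = 0, allow_zero_lower = FALSE)
  homologue <- as.integer(homologue)
  stop_if(homologue != n_cl,
          sprintf("peak '%s': homologue (%d) must equal n_cl (%d); mixed-homologue coelutions are not supported",
                  peak_id, homologue, n_cl))
  structure(list(peak_id = peak_id, n_cl = n_cl, homologue = homologue,
                 log_kow = log_kow, k_h = k_h, k_d = k_d, mw = mw),
            class = "congener")
}

#' @export
print.congener <- function(x, ...) {
  cat(sprintf("<congener> %s  (%d Cl, %s)  logKow=%.2f  Kh=%.3g  Kd=%.3g L/kg  MW=%.1f\n",
              x$peak_id, x$n_cl, if (is_lc(x)) "LC" else "HC",
              x$log_kow, x$k_h, x$k_d, x$mw))
  invisible(x)
}

#' Is a congener lower-chlorinated (LC)?
#'
#' Lower-chlorinated PCBs are defined as congeners with three or fewer
#' chlorine substituents; they are the more volatile, inhalation-relevant
#' fraction and the preferred substrates of aerobic biphenyl-pathway
#' degraders.
#'
#' @param x a `congener`
#' @return `TRUE` iff the chlorine count is <= 3
#' @export
is_lc <- function(x) {
  stop_if(!inherits(x, "congener"), "x must be a congener")
  x$n_cl <= 3L
}

.congener_cols <- c("peak_id", "n_cl", "log_kow", "k_h", "k_d", "mw")

#' Read a congener property table from CSV
#'
#' Expected columns (header required, "." decimal):
#' `peak_id,n_cl,log_kow,k_h,k_d,mw`. Each row becomes one [congener];
#' duplicate `peak_id`s and invariant violations are rejected with an error
#' naming the offending row.
#'
#' @param path path to the CSV file
#' @return a named list of `congener` objects (names are peak ids)
#' @seealso [write_congeners()], [default_congeners()]
#' @export
load_congeners <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.congener_cols, names(df))
  stop_if(length(missing) > 0,
          "congener CSV missing column(s): ", paste(missing, collapse = ", "))
  for (col in setdiff(.congener_cols, "peak_id"))
    stop_if(!is.numeric(df[[col]]),
            sprintf("congener CSV column '%s' is not numeric", col))
  dup <- df$peak_id[duplicated(df$peak_id)]
  stop_if(length(dup) > 0, "duplicate peak_id in congener CSV: ",
          paste(unique(dup), collapse = ", "))
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    out[[i]] <- tryCatch(
      congener(df$peak_id[i], df$n_cl[i], df$log_kow[i], df$k_h[i],
               df$k_d[i], df$mw[i]),
      error = function(e) stop(sprintf("congener CSV row %d: %s", i,
                                       conditionMessage(e)), call. = FALSE))
  }
  names(out) <- df$peak_id
  out
}

#' Write a congener list to CSV
#'
#' Inverse of [load_congeners()]: the written file round-trips all fields.
#'
#' @param congeners named list of `congener` objects
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_congeners <- function(congeners, path) {
  df <- do.call(rbind, lapply(congeners, function(cg)
    data.frame(peak_id = cg$peak_id, n_cl = cg$n_cl, log_kow = cg$log_kow,
               k_h = cg$k_h, k_d = cg$k_d, mw = cg$mw)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Illustrative default congener set
#'
#' Three peaks spanning the dichloro to pentachloro range: PCB 4
#' (2,2'-dichlorobiphenyl) and PCB 19 (2,2',6-trichlorobiphenyl), the two
#' congeners most relevant to aerobic lower-chlorinated-PCB degradation, and
#' PCB 118 as a higher-chlorinated representative. The property values are
#' ILLUSTRATIVE round numbers of realistic magnitude, not a literature
#' compilation; supply your own CSV via [load_congeners()] for real work.
#'
#' @return a named list of `congener` objects
#' @export
default_congeners <- function() {
  lst <- list(
    congener("PCB4",   n_cl = 2, log_kow = 4.65, k_h = 0.012, k_d = 2500,  mw = 223.10),
    congener("PCB19",  n_cl = 3, log_kow = 5.02, k_h = 0.015, k_d = 5000,  mw = 257.54),
    congener("PCB118", n_cl = 5, log_kow = 6.74, k_h = 0.006, k_d = 50000, mw = 326.43))
  names(lst) <- vapply(lst, `[[`, "", "peak_id")
  lst
}
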