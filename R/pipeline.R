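# Exposure-by-outcome analysis grid: instrument selection -> harmonization ->
# IVW (Wald fallback at one instrument) -> sensitivity, with per-cell status
# and a per-stage instrument audit.

#' Build an analysis plan for the MR grid
#'
#' @param exposures Named list of [sumstats()] objects.
#' @param outcomes Named list of [sumstats()] objects.
#' @param ld An [ld_matrix()] covering the exposures' SNPs, or a named list
#'   of matrices keyed by exposure name.
#' @param p_threshold,clump_r2,clump_kb Instrument-selection parameters.
#' @param min_snps_ivw Minimum harmonized pairs for IVW (default 2; a single
#'   pair falls back to the Wald ratio).
#' @param min_snps_report Below this many harmonized pairs a cell is marked
#'   `insufficient_snps` (default 1).
#' @return A validated list of class `analysis_plan`.
#' @export
analysis_plan <- function(exposures, outcomes, ld, p_threshold = 5e-6,
                          clump_r2 = 0.001, clump_kb = 10000,
                          min_snps_ivw = 2, min_snps_report = 1) {
  if (length(exposures) == 0) stop("plan needs at least one exposure")
  if (length(outcomes) == 0) stop("plan needs at least one outcome")
  if (is.null(names(exposures)) || any(names(exposures) == "") ||
      anyDuplicated(names(exposures))) {
    stop("exposures must be uniquely named")
  }
  if (is.null(names(outcomes)) || any(names(outcomes) == "") ||
      anyDuplicated(names(outcomes))) {
    stop("outcomes must be uniquely named")
  }
  for (s in c(exposures, outcomes)) stopifnot(inherits(s, "sumstats"))
  structure(list(exposures = exposures, outcomes = outcomes, ld = ld,
                 p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_kb = clump_kb, min_snps_ivw = min_snps_ivw,
                 min_snps_report = min_snps_report),
            class = "analysis_plan")
}

empty_cell <- function(exposure, outcome) {
  data.frame(
    exposure = exposure, outcome = outcome, status = "insufficient_snps",
    method = NA_character_, n_snps = 0L, beta = NA_real_, se = NA_real_,
    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
    strength = NA_character_, stars = "",
    q_stat = NA_real_, q_df = NA_integer_, q_pval = NA_real_,
    egger_intercept = NA_real_, egger_intercept_se = NA_real_,
    egger_intercept_pval = NA_real_,
    n_instruments_initial = 0L, n_after_clump = 0L,
    n_found_in_outcome = 0L, n_after_harmonization = 0L,
    stringsAsFactors = FALSE
  )
}

analyze_cell <- function(exposure, outcome, instruments, plan) {
  cell <- empty_cell(exposure$trait_name, outcome$trait_name)
  hset <- harmonize(exposure, outcome, instruments)
  n_found <- sum(hset$dispositions$action != "missing_in_outcome")
  n_pairs <- nrow(hset$pairs)
  cell$n_found_in_outcome <- n_found
  cell$n_after_harmonization <- n_pairs
  if (n_pairs < plan$min_snps_report) return(cell)
  fit <- mr_ivw(hset)   # Wald fallback at n = 1 happens inside
  cell$status <- "ok"
  cell$method <- fit$method
  cell$n_snps <- fit$n_snps
  cell$beta <- fit$beta_hat; cell$se <- fit$se_hat
  cell$or <- fit$or_hat; cell$ci_low <- fit$ci_low; cell$ci_high <- fit$ci_high
  cell$pval <- fit$pval; cell$strength <- fit$strength
  cell$stars <- strength_stars(fit$strength)
  if (n_pairs >= max(2, plan$min_snps_ivw)) {
    sens <- mr_sensitivity(hset, fit)
    cell$q_stat <- sens$q_stat; cell$q_df <- sens$q_df; cell$q_pval <- sens$q_pval
    cell$egger_intercept <- sens$egger_intercept
    cell$egger_intercept_se <- sens$egger_intercept_se
    cell$egger_intercept_pval <- sens$egger_intercept_pval
  }
  cell
}

#' Run the full exposure-by-outcome MR grid
#'
#' Per cell: select instruments (P filter + LD clump) -> harmonize -> IVW
#' (Wald-ratio fallback with a single instrument) -> Cochran's Q and
#' MR-Egger where degrees of freedom permit (Q/IVW at 2+, Egger at 3+) ->
#' strength tier and star annotation.  Cells with fewer harmonized pairs than
#' `min_snps_report` are marked `insufficient_snps` (the gray boxes of a
#' result heatmap); a failing input fails its cells, not the grid.  Per-stage
#' counts (selected -> clumped -> found-in-outcome -> harmonized) are
#' recorded on every row, giving the instrument-count audit.
#'
#' @param plan An [analysis_plan()].
#' @return data.frame with one row per exposure-outcome cell, ordered by the
#'   plan's exposure then outcome names; attribute `n_failed` counts cells
#'   that raised errors.
#' @export
run_grid <- function(plan) {
  stopifnot(inherits(plan, "analysis_plan"))
  rows <- list()
  n_failed <- 0L
  for (ex_name in names(plan$exposures)) {
    exposure <- plan$exposures[[ex_name]]
    ld <- if (inherits(plan$ld, "ld_matrix")) plan$ld else plan$ld[[ex_name]]
    sel <- tryCatch({
      cand <- filter_by_pvalue(exposure, plan$p_threshold)
      inst <- ld_clump(cand, ld, plan$clump_r2, plan$clump_kb,
                       exposure_name = ex_name, p_threshold = plan$p_threshold)
      list(cand = cand, inst = inst)
    }, error = function(e) e)
    for (out_name in names(plan$outcomes)) {
      cell <- tryCatch({
        if (inherits(sel, "error")) stop(conditionMessage(sel))
        cl <- analyze_cell(exposure, plan$outcomes[[out_name]],
                           sel$inst, plan)
        cl$n_instruments_initial <- nrow(sel$cand)
        cl$n_after_clump <- length(sel$inst$snp_ids)
        cl$exposure <- ex_name
        cl$outcome <- out_name
        cl
      }, error = function(e) {
        warning("cell ", ex_name, " x ", out_name, " failed: ",
                conditionMessage(e))
        n_failed <<- n_failed + 1L
        cl <- empty_cell(ex_name, out_name)
        cl$status <- "skipped"
        cl
      })
      rows[[length(rows) + 1]] <- cell
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  attr(grid, "n_failed") <- n_failed
  grid
}

#' Render the heatmap-style summary table of a grid
#'
#' One row per cell with OR, P, the star annotation (`***` strong, `**`
#' moderate, `*` weak) and the status token; insufficient cells carry no
#' stars.
#'
#' @param cells The data.frame from [run_grid()].
#' @return data.frame with columns exposure, outcome, or, pval, stars, status.
#' @export
render_heatmap_table <- function(cells) {
  data.frame(
    exposure = cells$exposure, outcome = cells$outcome,
    or = cells$or, pval = cells$pval,
    stars = ifelse(cells$status == "ok", cells$stars, ""),
    status = cells$status,
    stringsAsFactors = FALSE
  )
}

#' Plot the grid as an OR heatmap with star annotations
#'
#' Blue-to-red gradient around OR = 1; gray cells mark insufficient SNPs.
#' Requires ggplot2.
#'
#' @param cells The data.frame from [run_grid()].
#' @return A ggplot object.
#' @export
plot_mr_heatmap <- function(cells) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_mr_heatmap requires ggplot2")
  }
  cells$label <- ifelse(cells$status == "ok", cells$stars, "")
  ggplot2::ggplot(cells, ggplot2::aes(x = outcome, y = exposure)) +
    ggplot2::geom_tile(ggplot2::aes(fill = or), color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = label)) +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "steelblue",
                                  mid = "white", high = "firebrick",
                                  na.value = "grey70") +
    ggplot2::labs(fill = "OR", x = NULL, y = NULL)
}

#' Write the grid report as a deterministic TSV
#'
#' Numeric formatting is fixed (15 significant digits), so identical grids
#' produce byte-identical files.
#'
#' @param cells The data.frame from [run_grid()].
#' @param path Output path.
#' @export
write_grid_report <- function(cells, path) {
  out <- cells
  num <- vapply(out, is.numeric, logical(1))
  for (col in names(out)[num]) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.15g", out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
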