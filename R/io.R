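#' Read and write per-cell fusome volume tables
#'
#' The CSV schema is `cyst_id, stage, cell_label, volume_um3` (extra
#' columns pass through).
#'
#' @param path CSV file path.
#' @param volumes a volume table data frame.
#' @return `read_volume_table` returns the data frame;
#'   `write_volume_table` returns `path` invisibly.
#' @export
read_volume_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cyst_id", "stage", "cell_label", "volume_um3")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("volume table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab$stage <- as.integer(tab$stage)
  tab$cell_label <- as.integer(tab$cell_label)
  tab
}

#' @rdname read_volume_table
#' @export
write_volume_table <- function(volumes, path) {
  utils::write.csv(volumes, path, row.names = FALSE)
  invisible(path)
}

#' Import a supplementary per-cyst volume sheet
#'
#' Reader for the layout of the published supplementary volume spreadsheet
#' ("female fusome volumes"), exported to CSV: one row per cell with
#' columns for the cyst size, a per-cyst sample identifier, the canonical
#' cell number and the measured fusome volume. Column names are mapped via
#' `column_map`; defaults cover the common header spellings.
#'
#' @param path CSV export of the spreadsheet.
#' @param column_map named character vector mapping the four schema columns
#'   to spreadsheet headers.
#' @return a volume table (see [read_volume_table()]).
#' @export
read_s1_volume_table <- function(path,
                                 column_map = c(cyst_id = "Sample",
                                                stage = "Cyst size",
                                                cell_label = "Cell",
                                                volume_um3 = "Volume")) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(unname(column_map), names(raw))
  if (length(miss))
    stop("spreadsheet export missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- data.frame(cyst_id = raw[[column_map["cyst_id"]]],
                    stage = as.integer(raw[[column_map["stage"]]]),
                    cell_label = as.integer(raw[[column_map["cell_label"]]]),
                    volume_um3 = as.numeric(raw[[column_map["volume_um3"]]]))
  out
}

#' Export a fit as JSON
#'
#' @param fit a [fit_fusome_growth()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fusome_fit"))
  obj <- list(alpha = fit$alpha, beta = fit$beta, error = fit$error,
              alpha_range5 = attr(fit$region5, "alpha_range"),
              beta_range5 = attr(fit$region5, "beta_range"),
              plug_volumes = as.list(fit$plugs$v),
              n_cysts = as.list(fit$n_cysts))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the reconstruction/fitting pipeline
#'
#' Ties the stages together the way the imaging pipeline runs: rendered (or
#' loaded) image pairs are reconstructed per sample; female mode yields a
#' per-cell volume-fraction table and, optionally, a growth-model fit; male
#' mode yields a connected-cell census with embeddability verdicts. A
#' failing sample is skipped with a warning, not a crash.
#'
#' @param samples list of samples; each a list with elements `fusome` and
#'   `rings` ([voxel_grid()]s) and optionally `id`.
#' @param mode `"female"` or `"male"`.
#' @param cutoff probability threshold.
#' @param fit (female mode) also fit the growth model to the resulting
#'   table? Requires at least one cyst per stage.
#' @param grid_step grid step forwarded to [fit_fusome_growth()].
#' @return list with `table` (female: per-cell rows `cyst_id, stage,
#'   cell_label, volume_um3, fraction`; male: census rows), `fit` (a
#'   `fusome_fit` or `NULL`), `failures` (character vector of skipped
#'   sample ids), and `config`.
#' @export
run_pipeline <- function(samples, mode = c("female", "male"), cutoff = 0.5,
                         fit = FALSE, grid_step = 0.005) {
  mode <- match.arg(mode)
  rows <- list(); failures <- character(0)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    id <- if (!is.null(s$id)) s$id else sprintf("sample%03d", i)
    res <- tryCatch(
      reconstruct_cyst(s$fusome, s$rings, mode = mode, cutoff = cutoff),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("sample ", id, " skipped: ", conditionMessage(res),
              call. = FALSE)
      failures <- c(failures, id)
      next
    }
    if (mode == "female") {
      fr <- res$fragments
      rows[[length(rows) + 1L]] <- data.frame(
        cyst_id = id, stage = nrow(fr), cell_label = fr$label,
        volume_um3 = fr$volume_um3, fraction = fr$fraction)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        cyst_id = id,
        component = seq_along(res),
        n_cells = vapply(res, `[[`, integer(1), "n_cells"),
        power_of_2 = vapply(res, `[[`, logical(1), "power_of_2"),
        embeddable = vapply(res, `[[`, logical(1), "embeddable"),
        volume_um3 = vapply(res, `[[`, numeric(1), "volume_um3"))
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else NULL
  fit_obj <- NULL
  if (fit && mode == "female" && !is.null(tab))
    fit_obj <- fit_fusome_growth(tab, grid_step = grid_step)
  list(table = tab, fit = fit_obj, failures = failures,
       config = list(mode = mode, cutoff = cutoff))
}

#' Census of simulated fragmented male cysts
#'
#' Renders `n_cysts` male-style cysts (elongated layout, bridges broken
#' with probability `p_frag`), runs the male pipeline on each, and reports
#' per-component connected-cell counts and the fraction of cysts whose
#' largest component connects a power-of-2 number of cells.
#'
#' @param n_cysts number of simulated cysts.
#' @param tree topology to render (default the canonical 16-cell tree).
#' @param p_frag bridge-breakage probability.
#' @param seed integer seed.
#' @param ... passed to [render_config()].
#' @return list with `census` (per-cyst data frame for the largest
#'   component: `n_cells`, `power_of_2`, `embeddable`) and
#'   `frac_power_of_2`.
#' @export
simulate_male_census <- function(n_cysts, tree = canonical_max_branched(16),
                                 p_frag = 0.2, seed = 1L, ...) {
  rows <- list()
  for (i in seq_len(n_cysts)) {
    img <- render_cyst(render_config(tree, p_frag = p_frag,
                                     seed = seed + 131L * i, ...))
    res <- reconstruct_cyst(img$fusome, img$rings, mode = "male")
    top <- res[[1]]  # components come largest-first
    rows[[i]] <- data.frame(cyst = i, n_cells = top$n_cells,
                            power_of_2 = top$power_of_2,
                            embeddable = top$embeddable)
  }
  census <- do.call(rbind, rows)
  list(census = census, frac_power_of_2 = mean(census$power_of_2))
}
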