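#' Z-projection by slice summation
#'
#' Collapses a Z-stack into one image by pixelwise summation across slices.
#'
#' @param x a 3-D array (`ny x nx x n_slices`), a 2-D matrix (returned
#'   unchanged), or a [simulate_selectivity_stack()] object together with
#'   `channel`.
#' @param channel channel name when `x` is a `selectivity_stack`
#'   (`"antibody"`, `"ligand"`, or `"nucleus"`).
#' @return 2-D numeric matrix.
#' @export
z_project_sum <- function(x, channel = NULL) {
  if (inherits(x, "selectivity_stack")) {
    stopifnot(!is.null(channel), channel %in% names(x$channels))
    x <- x$channels[[channel]]
  }
  if (is.matrix(x)) return(x)
  stopifnot(is.array(x), length(dim(x)) == 3, dim(x)[3] >= 1)
  apply(x, c(1, 2), sum)
}

#' Cell and nucleus masks for the selectivity pipeline
#'
#' Thin wrappers around [threshold_mask()] with the pipeline defaults:
#' Otsu threshold, morphological closing with a 3-pixel disc, hole filling,
#' and removal of objects under 50 pixels.
#'
#' @param projection 2-D summed projection of the antibody (cell) or
#'   nucleus channel.
#' @param threshold,min_object_px,closing_radius_px,fill_holes see
#'   [threshold_mask()].
#' @return A [new_mask()].
#' @export
build_cell_mask <- function(projection, threshold = NULL,
                            min_object_px = 50L, closing_radius_px = 3L,
                            fill_holes = TRUE) {
  threshold_mask(projection, threshold = threshold,
                 min_object_px = min_object_px,
                 closing_radius_px = closing_radius_px,
                 fill_holes = fill_holes)
}

#' @rdname build_cell_mask
#' @export
build_nucleus_mask <- function(projection, threshold = NULL,
                               min_object_px = 50L, closing_radius_px = 3L,
                               fill_holes = TRUE) {
  threshold_mask(projection, threshold = threshold,
                 min_object_px = min_object_px,
                 closing_radius_px = closing_radius_px,
                 fill_holes = fill_holes)
}

#' Quantify ligand signal within the cell-minus-nucleus region
#'
#' Sums the ligand channel across slices, restricts it to the cell mask
#' minus the nucleus mask, and reports the region mean corrected for
#' background. The background is the mean summed intensity outside a
#' `background_margin_px` dilation of the cell mask. The record passes the
#' background filter only when the (uncorrected) region mean is strictly
#' above the background.
#'
#' @param ligand a 3-D ligand Z-stack, a 2-D summed projection, or a
#'   [simulate_selectivity_stack()] (its `"ligand"` channel is used).
#' @param cell_mask,nucleus_mask logical matrices matching the projection.
#' @param background_margin_px dilation margin in pixels (default 5).
#' @param cell_type,state,spacing_nm condition labels stored in the record.
#' @return One-row `data.frame` (class `selectivity_record`): condition
#'   labels, `cell_area_px`, `region_area_px`, `region_mean`,
#'   `background_mean`, `corrected` (`max(0, region_mean -
#'   background_mean)`), `normalized` (`NA` until [normalize_global()]),
#'   `passed_background_filter`.
#' @export
quantify_signal <- function(ligand, cell_mask, nucleus_mask,
                            background_margin_px = 5L,
                            cell_type = NA_character_,
                            state = NA_character_,
                            spacing_nm = NA_real_) {
  if (inherits(ligand, "selectivity_stack")) {
    if (is.na(spacing_nm)) spacing_nm <- ligand$scaffold_spacing_nm
    ligand <- ligand$channels$ligand
  }
  proj <- z_project_sum(ligand)
  cell_m <- matrix(as.logical(cell_mask), nrow(proj), ncol(proj))
  nuc_m <- matrix(as.logical(nucleus_mask), nrow(proj), ncol(proj))
  stopifnot(all(dim(cell_m) == dim(proj)), all(dim(nuc_m) == dim(proj)))
  region <- cell_m & !nuc_m
  if (!any(region))
    stop("cell-minus-nucleus region is empty (cell mask ", sum(cell_m),
         " px, nucleus mask ", sum(nuc_m), " px)")
  bg <- background_outside_mask(proj, cell_m, background_margin_px)
  region_mean <- mean(proj[region])
  corrected <- max(0, region_mean - bg)
  structure(data.frame(cell_type = cell_type, state = state,
                       spacing_nm = spacing_nm,
                       cell_area_px = sum(cell_m),
                       region_area_px = sum(region),
                       region_mean = region_mean,
                       background_mean = bg,
                       corrected = corrected,
                       normalized = NA_real_,
                       passed_background_filter = region_mean > bg),
            class = c("selectivity_record", "data.frame"))
}

#' Keep only records with signal above background
#'
#' Retains records whose uncorrected region mean is strictly greater than
#' the background estimate; removed records are reported via `message()`.
#'
#' @param records data.frame of [quantify_signal()] records (rows may be
#'   concatenated with `rbind`).
#' @return The passing subset, same columns.
#' @export
filter_above_background <- function(records) {
  stopifnot(is.data.frame(records),
            "passed_background_filter" %in% names(records))
  drop <- !records$passed_background_filter
  if (any(drop))
    message(sum(drop), " record(s) removed: region mean not above ",
            "background (rows ", paste(which(drop), collapse = ", "), ")")
  records[!drop, , drop = FALSE]
}

#' Globally normalize background-corrected signals
#'
#' Divides every record's corrected value by the maximum corrected value of
#' the comparison set, so the strongest condition maps to 1. Scale-invariant:
#' multiplying all inputs by any positive constant leaves the output
#' unchanged.
#'
#' @param records data.frame with a `corrected` column (>= 1 row).
#' @return `records` with the `normalized` column filled in.
#' @export
normalize_global <- function(records) {
  stopifnot(is.data.frame(records), "corrected" %in% names(records),
            nrow(records) >= 1)
  mx <- max(records$corrected)
  if (mx <= 0)
    stop("all corrected values are zero; global normalization undefined")
  records$normalized <- records$corrected / mx
  records
}

#' Condition statistics for selectivity records
#'
#' For each (cell type, scaffold spacing): a one-way ANOVA of the
#' normalized signal across activation states. For each (cell type, state):
#' Welch two-sample t-tests between every pair of scaffold spacings, with
#' optional Holm adjustment. Groups with fewer than two records are skipped
#' with a warning.
#'
#' @param records normalized records (see [normalize_global()]); must carry
#'   `cell_type`, `state`, `spacing_nm`, and a `value` column selected by
#'   `value_col`.
#' @param value_col column analysed (default `"normalized"`).
#' @param adjust `"none"` (default, raw p-values) or `"holm"`.
#' @return A list of class `condition_stats`: `anova` (data.frame
#'   `cell_type`, `spacing_nm`, `F`, `p`, `df1`, `df2`, `n`) and `ttests`
#'   (data.frame `cell_type`, `state`, `spacing_a`, `spacing_b`, `t`, `p`,
#'   `p_adj`, `n_a`, `n_b`).
#' @export
compare_conditions <- function(records, value_col = "normalized",
                               adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(records),
            all(c("cell_type", "state", "spacing_nm", value_col) %in%
                  names(records)))
  v <- records[[value_col]]

  anova_rows <- list()
  for (ct in unique(records$cell_type)) {
    for (sp in unique(records$spacing_nm[records$cell_type == ct])) {
      sub <- records$cell_type == ct & records$spacing_nm == sp
      sizes <- table(records$state[sub])
      if (length(sizes) < 2 || any(sizes < 2)) {
        warning("ANOVA skipped for cell_type=", ct, ", spacing=", sp,
                ": need >= 2 states with >= 2 records each")
        next
      }
      fit <- aov(v[sub] ~ factor(records$state[sub]))
      tab <- summary(fit)[[1]]
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        cell_type = ct, spacing_nm = sp,
        F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
        df1 = tab[1, "Df"], df2 = tab[2, "Df"], n = sum(sub))
    }
  }

  tt_rows <- list()
  for (ct in unique(records$cell_type)) {
    for (st in unique(records$state[records$cell_type == ct])) {
      sub <- records[records$cell_type == ct & records$state == st, ]
      sps <- sort(unique(sub$spacing_nm))
      if (length(sps) < 2) next
      for (a in seq_len(length(sps) - 1)) for (b in (a + 1):length(sps)) {
        va <- sub[[value_col]][sub$spacing_nm == sps[a]]
        vb <- sub[[value_col]][sub$spacing_nm == sps[b]]
        if (length(va) < 2 || length(vb) < 2) {
          warning("t-test skipped for cell_type=", ct, ", state=", st,
                  ", spacings ", sps[a], " vs ", sps[b],
                  ": need >= 2 records per group")
          next
        }
        tt <- t.test(va, vb)  # Welch by default
        tt_rows[[length(tt_rows) + 1L]] <- data.frame(
          cell_type = ct, state = st,
          spacing_a = sps[a], spacing_b = sps[b],
          t = unname(tt$statistic), p = tt$p.value,
          n_a = length(va), n_b = length(vb))
      }
    }
  }
  anova_df <- if (length(anova_rows)) do.call(rbind, anova_rows) else
    data.frame(cell_type = character(), spacing_nm = numeric(),
               F = numeric(), p = numeric(), df1 = numeric(),
               df2 = numeric(), n = integer())
  tt_df <- if (length(tt_rows)) do.call(rbind, tt_rows) else
    data.frame(cell_type = character(), state = character(),
               spacing_a = numeric(), spacing_b = numeric(), t = numeric(),
               p = numeric(), n_a = integer(), n_b = integer())
  tt_df$p_adj <- if (nrow(tt_df)) p.adjust(tt_df$p, method = adjust) else
    numeric(0)
  structure(list(anova = anova_df, ttests = tt_df, adjust = adjust),
            class = "condition_stats")
}

#' @export
print.condition_stats <- function(x, ...) {
  cat("<condition_stats>\nANOVA across activation states:\n")
  print(x$anova, row.names = FALSE)
  cat("Pairwise t-tests between scaffolds (", x$adjust, " adjustment):\n",
      sep = "")
  print(x$ttests, row.names = FALSE)
  invisible(x)
}

#' Run the full selectivity pipeline on a set of stacks
#'
#' For each stack: sum-project the antibody and nucleus channels, build the
#' cell and nucleus masks, quantify the ligand signal in the
#' cell-minus-nucleus region, then filter below-background records and
#' normalize globally over the whole comparison set.
#'
#' @param stacks list of [simulate_selectivity_stack()] objects (or lists
#'   with a `channels` element of the same shape).
#' @param conditions optional data.frame with one row per stack
#'   (`cell_type`, `state`, `spacing_nm`) overriding labels taken from the
#'   stacks.
#' @param background_margin_px see [quantify_signal()].
#' @return A list of class `selectivity_result`: `records` (all records,
#'   before filtering), `passing` (filtered + normalized records).
#' @export
run_selectivity_pipeline <- function(stacks, conditions = NULL,
                                     background_margin_px = 5L) {
  stopifnot(is.list(stacks), length(stacks) >= 1)
  recs <- lapply(seq_along(stacks), function(k) {
    st <- stacks[[k]]
    cell_proj <- z_project_sum(st$channels$antibody)
    nuc_proj <- z_project_sum(st$channels$nucleus)
    cm <- build_cell_mask(cell_proj)
    nm <- build_nucleus_mask(nuc_proj)
    lab <- if (!is.null(conditions)) conditions[k, ] else
      data.frame(cell_type = NA_character_, state = NA_character_,
                 spacing_nm = st$scaffold_spacing_nm)
    quantify_signal(st$channels$ligand, cm, nm,
                    background_margin_px = background_margin_px,
                    cell_type = lab$cell_type, state = lab$state,
                    spacing_nm = lab$spacing_nm)
  })
  records <- do.call(rbind, recs)
  passing <- filter_above_background(records)
  if (nrow(passing) > 0 && max(passing$corrected) > 0)
    passing <- normalize_global(passing)
  structure(list(records = records, passing = passing),
            class = "selectivity_result")
}
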