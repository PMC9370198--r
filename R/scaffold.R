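#' Bivalent Y-scaffold geometry
#'
#' Geometry of a three-armed DNA junction presenting two ligands: base
#' pairs between the junction and each ligand attachment, the helical rise
#' per base pair (B-DNA canonical 0.34 nm), an optional junction gap, and
#' the angle between the two ligand arms (180 degrees is the maximal
#' arm-to-arm conformation).
#'
#' @param arm1_bp,arm2_bp base pairs per arm (>= 0).
#' @param rise_per_bp_nm helical rise, nm per base pair (> 0).
#' @param junction_gap_nm extra separation contributed by the junction, nm.
#' @param arm_angle_deg angle between arms in (0, 180].
#' @return An object of class `scaffold_geometry`.
#' @export
scaffold_geometry <- function(arm1_bp, arm2_bp, rise_per_bp_nm = 0.34,
                              junction_gap_nm = 0, arm_angle_deg = 180) {
  stopifnot(arm1_bp >= 0, arm2_bp >= 0, rise_per_bp_nm > 0,
            junction_gap_nm >= 0,
            arm_angle_deg > 0, arm_angle_deg <= 180)
  structure(list(arm1_bp = arm1_bp, arm2_bp = arm2_bp,
                 rise_per_bp_nm = rise_per_bp_nm,
                 junction_gap_nm = junction_gap_nm,
                 arm_angle_deg = arm_angle_deg),
            class = "scaffold_geometry")
}

#' End-to-end ligand spacing of a Y-scaffold
#'
#' Law-of-cosines distance between the two arm tips,
#' `sqrt(L1^2 + L2^2 - 2 L1 L2 cos(angle))` with `L = bp * rise`, plus the
#' junction gap. At 180 degrees this reduces to
#' `(arm1_bp + arm2_bp) * rise + junction_gap`. Both the exact value and
#' its nanometer roundings are reported (`rounded_nm` to the nearest
#' nanometer, `rounded_up_nm` to the next full nanometer).
#'
#' @param geom a [scaffold_geometry()].
#' @return List with `exact_nm`, `rounded_nm`, `rounded_up_nm`.
#' @examples
#' end_to_end_spacing(scaffold_geometry(10, 10))  # 6.8 nm -> 7 nm
#' @export
end_to_end_spacing <- function(geom) {
  stopifnot(inherits(geom, "scaffold_geometry"))
  l1 <- geom$arm1_bp * geom$rise_per_bp_nm
  l2 <- geom$arm2_bp * geom$rise_per_bp_nm
  theta <- geom$arm_angle_deg * pi / 180
  d <- sqrt(max(0, l1^2 + l2^2 - 2 * l1 * l2 * cos(theta))) +
    geom$junction_gap_nm
  list(exact_nm = d, rounded_nm = round(d), rounded_up_nm = ceiling(d))
}

#' Symmetric arm lengths for a target ligand spacing
#'
#' Smallest symmetric design `(b, b)` whose fully extended span
#' `2 b * rise` reaches within half a nanometer below the target; when the
#' neighboring design achieves a smaller absolute error the tie is broken
#' toward that smaller error. Targets below the reach of a single base pair
#' per arm return `(1, 1)` with a warning.
#'
#' @param target_nm desired ligand spacing (> 0).
#' @param rise_per_bp_nm helical rise, nm per base pair.
#' @param max_bp search bound per arm (default 200).
#' @return List with `arm_bp` (per-arm base pairs), `achieved_nm`,
#'   `error_nm` (achieved minus target), and the corresponding
#'   [scaffold_geometry()].
#' @examples
#' arms_for_spacing(7)   # (10, 10) bp: 6.8 nm
#' arms_for_spacing(24)  # (35, 35) bp: 23.8 nm
#' @export
arms_for_spacing <- function(target_nm, rise_per_bp_nm = 0.34,
                             max_bp = 200L) {
  stopifnot(rise_per_bp_nm > 0, max_bp >= 1)
  if (target_nm <= 0) stop("target_nm must be > 0")
  b <- seq_len(max_bp)
  achieved <- 2 * b * rise_per_bp_nm
  best <- b[which.min(abs(achieved - target_nm))]
  if (target_nm < 2 * rise_per_bp_nm) {
    warning("target ", target_nm, " nm is below the reach of one base pair ",
            "per arm; returning (1, 1)")
    best <- 1L
  }
  geom <- scaffold_geometry(best, best, rise_per_bp_nm)
  list(arm_bp = best, achieved_nm = 2 * best * rise_per_bp_nm,
       error_nm = 2 * best * rise_per_bp_nm - target_nm, geometry = geom)
}

#' Rigidity check against the dsDNA persistence length
#'
#' An arm behaves as a rigid rod while its contour length stays below the
#' double-stranded DNA persistence length (~50 nm, ~150 base pairs). The
#' scaffold is flagged rigid only when every ligand arm is strictly below
#' the threshold.
#'
#' @param geom a [scaffold_geometry()].
#' @param persistence_nm persistence length threshold (default 50 nm).
#' @return List with `rigid` (logical), `ratio` (longest arm contour length
#'   over the persistence length), `arm_lengths_nm`.
#' @examples
#' rigidity_check(scaffold_geometry(10, 10))  # ratio 0.068, rigid
#' @export
rigidity_check <- function(geom, persistence_nm = 50) {
  stopifnot(inherits(geom, "scaffold_geometry"), persistence_nm > 0)
  lens <- c(geom$arm1_bp, geom$arm2_bp) * geom$rise_per_bp_nm
  list(rigid = all(lens < persistence_nm),
       ratio = max(lens) / persistence_nm,
       arm_lengths_nm = lens)
}
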