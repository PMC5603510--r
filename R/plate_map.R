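WELL_ROLES <- c("test", "blank", "vehicle", "positive_chronotrope",
                "negative_chronotrope", "lethal_control")

# 384-well grid labels, row-major: A1..A24, B1..B24, ..., P24.
well_grid_384 <- function() {
  rows <- LETTERS[1:16]
  cols <- 1:24
  as.vector(t(outer(rows, cols, paste0)))
}

#' Lay out screening plates
#'
#' Assigns every compound x concentration x replicate combination to a well
#' on one or more 384-well plates (rows A-P, columns 1-24).  Each plate
#' carries the full set of reference wells: blank (medium) wells plus
#' vehicle (DMSO), positive-chronotrope (caffeine), negative-chronotrope
#' (nifedipine) and lethal (ethanol) controls.  Control wells occupy the
#' first columns; test wells then fill row-major across the remaining
#' columns.  When demand exceeds one plate's test capacity, additional
#' plates are created automatically, each with its own control block.
#'
#' @param registry A `compound_registry`.
#' @param concentrations Test concentrations in micromolar (default 0.1, 1
#'   and 10).
#' @param replicates Wells per compound x concentration (default 3).
#' @param n_blank Blank wells per plate (default 6).
#' @param n_reference Replicate wells per non-blank reference role per plate
#'   (default 3).
#' @return A tibble of class `plate_map` with columns `plate_id`, `well_id`,
#'   `role`, `compound_id`, `kinase_target`, `concentration_uM`, `replicate`.
#' @examples
#' pm <- make_plate_maps(make_registry(80, 23, seed = 7))
#' sum(pm$role == "test")  # 80 x 3 x 3 = 720
#' @export
make_plate_maps <- function(registry, concentrations = c(0.1, 1, 10),
                            replicates = 3L, n_blank = 6L, n_reference = 3L) {
  stopifnot(inherits(registry, "compound_registry"))
  if (length(concentrations) == 0) {
    stopf("`concentrations` must be nonempty")
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stopf("`concentrations` must be positive and finite")
  }
  assert_scalar_number(replicates, "replicates", min = 1)
  replicates <- as.integer(replicates)
  n_blank <- max(1L, as.integer(n_blank))
  n_reference <- max(1L, as.integer(n_reference))

  control_roles <- c(
    rep("blank", n_blank),
    rep("vehicle", n_reference),
    rep("positive_chronotrope", n_reference),
    rep("negative_chronotrope", n_reference),
    rep("lethal_control", n_reference)
  )
  n_control <- length(control_roles)
  # whole columns (16 wells each) are reserved for the control block
  reserved_cols <- ceiling(n_control / 16)
  capacity <- (24 - reserved_cols) * 16
  if (capacity < 1) stopf("control block leaves no room for test wells")

  wells <- well_grid_384()
  col_of <- as.integer(sub("^[A-P]", "", wells))
  control_wells <- wells[col_of <= reserved_cols][seq_len(n_control)]
  test_wells <- wells[col_of > reserved_cols]

  demand <- tidyr::expand_grid(
    compound_id = registry$compound_id,
    concentration_uM = sort(concentrations),
    replicate = seq_len(replicates)
  )
  demand$kinase_target <-
    registry$kinase_target[match(demand$compound_id, registry$compound_id)]
  n_plates <- ceiling(nrow(demand) / capacity)

  plates <- lapply(seq_len(n_plates), function(p) {
    lo <- (p - 1L) * capacity + 1L
    hi <- min(p * capacity, nrow(demand))
    block <- demand[lo:hi, ]
    ctrl_rep <- stats::ave(seq_along(control_roles), control_roles,
                           FUN = seq_along)
    tibble::tibble(
      plate_id = sprintf("P%02d", p),
      well_id = c(control_wells, test_wells[seq_len(nrow(block))]),
      role = c(control_roles, rep("test", nrow(block))),
      compound_id = c(rep(NA_integer_, n_control), block$compound_id),
      kinase_target = c(rep(NA_integer_, n_control), block$kinase_target),
      concentration_uM = c(rep(NA_real_, n_control), block$concentration_uM),
      replicate = c(as.integer(ctrl_rep), as.integer(block$replicate))
    )
  })
  out <- dplyr::bind_rows(plates)
  class(out) <- c("plate_map", class(out))
  out
}
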