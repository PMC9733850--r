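#' Build and validate a coarse-grained multilayer lipid configuration
#'
#' A `lipid_configuration` holds the bead coordinates of a stacked lipid
#' multilayer together with the labels the downstream order/tilt analyses
#' need: which lipid each bead belongs to, which bilayer the lipid sits in,
#' and the structural role of the bead along the chain.
#'
#' @param beads A data frame with one row per bead and columns `x`, `y`, `z`
#'   (coordinates in Angstrom), `lipid_id` (integer, one value per lipid),
#'   `layer_index` (integer, 0-based, bottom layer = 0) and `bead_role`
#'   (character, one of `"head"`, `"tail"`, `"terminal"`).
#' @param box Numeric length-3 vector of positive box lengths in Angstrom.
#' @param periodic Logical length-3 vector; whether each box direction is
#'   periodic. Default all `TRUE`.
#'
#' @return A tibble of beads with class `lipid_configuration` and attributes
#'   `box` and `periodic`.
#'
#' @details Validation enforces the structural invariants the analyses rely
#' on: every lipid has exactly one head bead and at least one terminal bead,
#' all beads of a lipid share one `layer_index`, layer indices are contiguous
#' `0..L-1`, all coordinates are finite and box lengths are positive.
#'
#' @examples
#' cfg <- lipid_configuration(
#'   tibble::tibble(
#'     x = c(0, 0, 0), y = 0, z = c(0, 15, 30),
#'     lipid_id = 1L, layer_index = 0L,
#'     bead_role = c("head", "tail", "terminal")
#'   ),
#'   box = c(100, 100, 100)
#' )
#' n_lipids(cfg)
#' @export
lipid_configuration <- function(beads, box, periodic = c(TRUE, TRUE, TRUE)) {
  beads <- tibble::as_tibble(beads)
  required <- c("x", "y", "z", "lipid_id", "layer_index", "bead_role")
  missing <- setdiff(required, names(beads))
  if (length(missing) > 0) {
    rlang::abort(paste0("beads is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "lamellaflex_invalid_configuration")
  }
  if (!is.numeric(box) || length(box) != 3 || any(!is.finite(box)) ||
      any(box <= 0)) {
    rlang::abort("box must be three positive finite lengths (Angstrom)",
                 class = "lamellaflex_invalid_configuration")
  }
  if (!is.logical(periodic) || length(periodic) != 3 || anyNA(periodic)) {
    rlang::abort("periodic must be three booleans",
                 class = "lamellaflex_invalid_configuration")
  }
  if (!all(is.finite(beads$x) & is.finite(beads$y) & is.finite(beads$z))) {
    rlang::abort("all bead coordinates must be finite",
                 class = "lamellaflex_invalid_configuration")
  }
  if (!all(beads$bead_role %in% c("head", "tail", "terminal"))) {
    rlang::abort("bead_role must be one of 'head', 'tail', 'terminal'",
                 class = "lamellaflex_invalid_configuration")
  }
  beads$lipid_id <- as.integer(beads$lipid_id)
  beads$layer_index <- as.integer(beads$layer_index)

  per_lipid <- dplyr::summarise(
    dplyr::group_by(beads, .data$lipid_id),
    n_head = sum(.data$bead_role == "head"),
    n_terminal = sum(.data$bead_role == "terminal"),
    n_layers = dplyr::n_distinct(.data$layer_index),
    .groups = "drop"
  )
  bad_head <- per_lipid$lipid_id[per_lipid$n_head != 1L]
  if (length(bad_head) > 0) {
    rlang::abort(
      paste0("lipid(s) without exactly one head bead: ",
             paste(utils::head(bad_head, 5), collapse = ", ")),
      class = "lamellaflex_degenerate_lipid")
  }
  bad_term <- per_lipid$lipid_id[per_lipid$n_terminal < 1L]
  if (length(bad_term) > 0) {
    rlang::abort(
      paste0("lipid(s) without a terminal bead: ",
             paste(utils::head(bad_term, 5), collapse = ", ")),
      class = "lamellaflex_degenerate_lipid")
  }
  bad_layer <- per_lipid$lipid_id[per_lipid$n_layers != 1L]
  if (length(bad_layer) > 0) {
    rlang::abort(
      paste0("lipid(s) spanning several layers: ",
             paste(utils::head(bad_layer, 5), collapse = ", ")),
      class = "lamellaflex_invalid_configuration")
  }
  layers <- sort(unique(beads$layer_index))
  if (!identical(layers, seq(0L, length(layers) - 1L))) {
    rlang::abort("layer indices must be contiguous 0..L-1",
                 class = "lamellaflex_invalid_configuration")
  }

  structure(beads,
            box = as.numeric(box),
            periodic = as.logical(periodic),
            class = c("lipid_configuration", class(tibble::tibble())))
}

#' @rdname lipid_configuration
#' @param x A `lipid_configuration`.
#' @export
config_box <- function(x) attr(x, "box")

#' @rdname lipid_configuration
#' @export
n_lipids <- function(x) dplyr::n_distinct(x$lipid_id)

#' @rdname lipid_configuration
#' @export
n_layers <- function(x) dplyr::n_distinct(x$layer_index)

#' @export
print.lipid_configuration <- function(x, ...) {
  box <- config_box(x)
  cat(sprintf(
    "<lipid_configuration> %d beads, %d lipids, %d layers; box %.1f x %.1f x %.1f A\n",
    nrow(x), n_lipids(x), n_layers(x), box[1], box[2], box[3]))
  NextMethod()
}

#' Build straight-chain lipids from a set of director vectors
#'
#' Constructs one rigid straight-chain lipid per supplied direction: head bead
#' at the base position, the remaining beads laid at `bond_length` steps along
#' the (normalized) direction, last bead flagged `terminal`. Useful for
#' constructing configurations with exactly known bond orientations, e.g. the
#' analytic limits of the P2 order parameter.
#'
#' @param directions Numeric matrix with 3 columns (one row per lipid) or a
#'   data frame with columns `dx`, `dy`, `dz`. Need not be normalized.
#' @param beads_per_lipid Beads per chain (>= 2). Default 3 so that each chain
#'   carries at least one non-head bond.
#' @param bond_length Bond length in Angstrom.
#' @param base Optional matrix/data frame of base positions (same shape as
#'   `directions`); defaults to a grid in the x-y plane.
#' @param box Box lengths in Angstrom; defaults to a box comfortably holding
#'   all beads.
#' @param layer_index Layer label applied to every chain (default 0).
#' @return A [lipid_configuration].
#' @examples
#' cfg <- chains_from_directors(rbind(c(0, 0, 1), c(1, 0, 0)))
#' order_parameter_p2(cfg)
#' @export
chains_from_directors <- function(directions, beads_per_lipid = 3,
                                  bond_length = 1.5, base = NULL, box = NULL,
                                  layer_index = 0L) {
  if (is.data.frame(directions)) {
    directions <- as.matrix(directions[, c("dx", "dy", "dz")])
  }
  directions <- matrix(as.numeric(directions), ncol = 3)
  if (beads_per_lipid < 2) {
    rlang::abort("beads_per_lipid must be >= 2",
                 class = "lamellaflex_invalid_parameter")
  }
  nrm <- sqrt(rowSums(directions^2))
  if (any(nrm == 0)) {
    rlang::abort("zero-length direction vector",
                 class = "lamellaflex_invalid_parameter")
  }
  directions <- directions / nrm
  n <- nrow(directions)
  if (is.null(base)) {
    side <- ceiling(sqrt(n))
    pitch <- 2 * (beads_per_lipid - 1) * bond_length + 10
    idx <- seq_len(n) - 1L
    base <- cbind((idx %% side + 0.5) * pitch,
                  (idx %/% side + 0.5) * pitch,
                  0)
  } else {
    base <- matrix(as.numeric(as.matrix(base)), ncol = 3)
  }
  steps <- (seq_len(beads_per_lipid) - 1) * bond_length
  beads <- tibble::tibble(
    x = rep(base[, 1], each = beads_per_lipid) +
      rep(directions[, 1], each = beads_per_lipid) * steps,
    y = rep(base[, 2], each = beads_per_lipid) +
      rep(directions[, 2], each = beads_per_lipid) * steps,
    z = rep(base[, 3], each = beads_per_lipid) +
      rep(directions[, 3], each = beads_per_lipid) * steps,
    lipid_id = rep(seq_len(n), each = beads_per_lipid),
    layer_index = as.integer(layer_index),
    bead_role = rep(
      c("head", rep("tail", max(0, beads_per_lipid - 2)), "terminal"), n)
  )
  if (is.null(box)) {
    ext <- (beads_per_lipid - 1) * bond_length
    box <- c(max(beads$x) + ext + 10, max(beads$y) + ext + 10,
             max(abs(beads$z)) + ext + 10)
    beads$z <- beads$z - min(beads$z)
  }
  lipid_configuration(beads, box = box)
}
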