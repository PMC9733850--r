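#' Per-lipid director vectors of a multilayer configuration
#'
#' The director of a lipid represents the overall orientation of the
#' molecule. By default it is the unit vector from the head bead to the mean
#' of the terminal bead(s), flipped if necessary so its z-component is
#' nonnegative (tilt is defined on 0-90 degrees). A principal-axis
#' alternative (leading singular vector of the centred bead coordinates,
#' sign-aligned with the head-to-tail sense) is available for comparison.
#'
#' @param config A [lipid_configuration].
#' @param method `"head_tail"` (default) or `"principal_axis"`.
#' @return A tibble with one row per lipid: `lipid_id`, `layer_index`,
#'   base position `x`, `y`, `z` (the head bead), unit director `dx`, `dy`,
#'   `dz`, and `tilt_deg`. Carries the source box as attribute `box` so that
#'   segmented statistics can bin laterally.
#' @examples
#' cfg <- simulate_multilayer(n_layers = 1, lipids_per_layer = 16,
#'                            amplitude = 0, seed = 1)
#' compute_directors(cfg)
#' @export
compute_directors <- function(config, method = c("head_tail", "principal_axis")) {
  method <- match.arg(method)
  beads <- tibble::as_tibble(config)

  heads <- dplyr::filter(beads, .data$bead_role == "head")
  heads <- dplyr::select(heads, "lipid_id", "layer_index",
                         hx = "x", hy = "y", hz = "z")
  terms <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(beads, .data$bead_role == "terminal"),
                    .data$lipid_id),
    tx = mean(.data$x), ty = mean(.data$y), tz = mean(.data$z),
    .groups = "drop")
  d <- dplyr::inner_join(heads, terms, by = "lipid_id")

  if (method == "head_tail") {
    vx <- d$tx - d$hx; vy <- d$ty - d$hy; vz <- d$tz - d$hz
  } else {
    axes <- vapply(split(beads, beads$lipid_id), function(b) {
      m <- cbind(b$x, b$y, b$z)
      m <- sweep(m, 2, colMeans(m))
      v <- svd(m, nu = 0, nv = 1)$v[, 1]
      head_i <- which(b$bead_role == "head")[1]
      tmean <- colMeans(cbind(b$x, b$y, b$z)[b$bead_role == "terminal", ,
                                             drop = FALSE])
      sense <- tmean - c(b$x[head_i], b$y[head_i], b$z[head_i])
      if (sum(v * sense) < 0) v <- -v
      v
    }, numeric(3))
    ord <- match(d$lipid_id, as.integer(colnames(axes)))
    vx <- unname(axes[1, ord]); vy <- unname(axes[2, ord])
    vz <- unname(axes[3, ord])
  }
  nrm <- sqrt(vx^2 + vy^2 + vz^2)
  if (any(nrm < 1e-12)) {
    bad <- d$lipid_id[nrm < 1e-12]
    rlang::abort(paste0("zero-length director for lipid(s): ",
                        paste(utils::head(bad, 5), collapse = ", ")),
                 class = "lamellaflex_degenerate_lipid")
  }
  vx <- vx / nrm; vy <- vy / nrm; vz <- vz / nrm
  flip <- vz < 0
  vx[flip] <- -vx[flip]; vy[flip] <- -vy[flip]; vz[flip] <- -vz[flip]

  out <- tibble::tibble(
    lipid_id = d$lipid_id, layer_index = d$layer_index,
    x = d$hx, y = d$hy, z = d$hz,
    dx = vx, dy = vy, dz = vz,
    tilt_deg = acos(pmin(pmax(vz, -1), 1)) * 180 / pi)
  attr(out, "box") <- attr(config, "box")
  out
}

#' Tilt angles of a director field
#'
#' Angle of each lipid director with respect to the membrane normal (z-axis),
#' folded to `[0, 90]` degrees.
#'
#' @param directors A director tibble from [compute_directors()], or a
#'   3-column matrix of direction vectors.
#' @return A tibble with `lipid_id`, `layer_index` (when available) and
#'   `tilt_deg`.
#' @export
tilt_angles <- function(directors) {
  if (is.matrix(directors)) {
    nrm <- sqrt(rowSums(directors^2))
    cz <- abs(directors[, 3]) / nrm
    return(tibble::tibble(
      lipid_id = seq_len(nrow(directors)),
      tilt_deg = acos(pmin(pmax(cz, -1), 1)) * 180 / pi))
  }
  tibble::tibble(
    lipid_id = directors$lipid_id,
    layer_index = directors$layer_index,
    tilt_deg = acos(pmin(pmax(abs(directors$dz), -1), 1)) * 180 / pi)
}

#' Histogram of lipid tilt angles
#'
#' Bins tilt angles on `[0, 90]` degrees with right-open bins (the last bin
#' closed) and reports the modal bin centre, ties broken toward the smaller
#' angle.
#'
#' @param angles Numeric vector of angles in degrees, or a tibble with a
#'   `tilt_deg` column (e.g. from [tilt_angles()]).
#' @param bin_width Bin width in degrees (> 0), default 1.
#' @return A `tilt_histogram`: tibble of `bin_lo`, `bin_hi`, `bin_center`,
#'   `count`, with attributes `modal_angle` (degrees) and `n_lipids`.
#'   Supports [ggplot2::autoplot()].
#' @examples
#' h <- tilt_histogram(c(9.7, 10.2, 10.4, 22.0))
#' modal_tilt(h)
#' @export
tilt_histogram <- function(angles, bin_width = 1) {
  if (is.data.frame(angles)) angles <- angles$tilt_deg
  angles <- as.numeric(angles)
  if (length(angles) < 1) {
    rlang::abort("need at least one angle",
                 class = "lamellaflex_invalid_parameter")
  }
  if (bin_width <= 0) {
    rlang::abort("bin_width must be positive",
                 class = "lamellaflex_invalid_parameter")
  }
  if (any(angles < 0 | angles > 90)) {
    rlang::abort("tilt angles must lie in [0, 90] degrees",
                 class = "lamellaflex_invalid_parameter")
  }
  edges <- seq(0, 90 + bin_width * 1e-9, by = bin_width)
  if (edges[length(edges)] < 90) edges <- c(edges, edges[length(edges)] + bin_width)
  nb <- length(edges) - 1
  idx <- pmin(findInterval(angles, edges, rightmost.closed = TRUE), nb)
  counts <- tabulate(idx, nbins = nb)
  centers <- (edges[-length(edges)] + edges[-1]) / 2
  modal <- centers[which.max(counts)]  # which.max takes the first = smaller angle
  structure(
    tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                   bin_center = centers, count = counts),
    modal_angle = modal, n_lipids = length(angles),
    class = c("tilt_histogram", class(tibble::tibble())))
}

#' @rdname tilt_histogram
#' @param x A `tilt_histogram`.
#' @export
modal_tilt <- function(x) attr(x, "modal_angle")

#' Second-rank (P2) bond order parameter
#'
#' Computes `P2 = mean((3 * cos(theta)^2 - 1) / 2)` over all chain bonds,
#' where `theta` is the angle of each bond either with the membrane normal
#' (z-axis) or with the director of the lipid the bond belongs to. The
#' director-referenced ("renormalized") variant removes the contribution of
#' whole-lipid tilt and isolates internal conformational order: for rigid
#' straight chains it is exactly 1 at any undulation amplitude or noise
#' level. P2 is 1 for perfect alignment along the reference, -0.5 for bonds
#' perpendicular to it, and 0 for isotropic orientations.
#'
#' Bonds are consecutive bead pairs within a lipid; the head-to-first-tail
#' bond is excluded by default (headgroup orientation is not tail order) but
#' can be kept with `include_head_bond = TRUE`.
#'
#' @param config A [lipid_configuration].
#' @param reference `"membrane_normal"` (default) or `"lipid_director"`.
#' @param include_head_bond Keep the head-to-first-tail bond? Default `FALSE`.
#' @param directors Optional precomputed [compute_directors()] result (used
#'   only for `reference = "lipid_director"`).
#' @return One-row tibble: `p2`, `reference`, `n_bonds`.
#' @examples
#' cfg <- chains_from_directors(rbind(c(0, 0, 1)))
#' order_parameter_p2(cfg)$p2  # 1
#' @export
order_parameter_p2 <- function(config,
                               reference = c("membrane_normal", "lipid_director"),
                               include_head_bond = FALSE,
                               directors = NULL) {
  reference <- match.arg(reference)
  beads <- tibble::as_tibble(config)
  beads <- beads[order(beads$lipid_id), ]
  same_lipid <- diff(beads$lipid_id) == 0L
  i1 <- which(same_lipid)
  i2 <- i1 + 1L
  if (!include_head_bond) {
    keep <- beads$bead_role[i1] != "head"
    i1 <- i1[keep]; i2 <- i2[keep]
  }
  if (length(i1) == 0) {
    rlang::abort("configuration has no qualifying bonds",
                 class = "lamellaflex_invalid_parameter")
  }
  bx <- beads$x[i2] - beads$x[i1]
  by <- beads$y[i2] - beads$y[i1]
  bz <- beads$z[i2] - beads$z[i1]
  nrm <- sqrt(bx^2 + by^2 + bz^2)
  if (any(nrm < 1e-12)) {
    rlang::abort("zero-length bond encountered",
                 class = "lamellaflex_degenerate_bond")
  }
  cos_theta <- if (reference == "membrane_normal") {
    bz / nrm
  } else {
    if (is.null(directors)) directors <- compute_directors(config)
    ord <- match(beads$lipid_id[i1], directors$lipid_id)
    (bx * directors$dx[ord] + by * directors$dy[ord] +
       bz * directors$dz[ord]) / nrm
  }
  tibble::tibble(
    p2 = mean((3 * cos_theta^2 - 1) / 2),
    reference = reference,
    n_bonds = length(cos_theta))
}

#' Segmented inter-layer correlation of lipid tilt
#'
#' Correlation of the scalar tilt angle between two layers of a multilayer:
#' `<theta(l1) * theta(l2)> / <theta(l1) * theta(l1)>`, where the averages
#' run over all within-segment lipid pairs, segments and frames. The x-y
#' plane is divided into a `segments x segments` lateral grid (half-open
#' bins, periodic wrap, membership by lipid base position); for each segment
#' the numerator accumulates the products of every (l1, l2) lipid pair and
#' the denominator the products of every (l1, l1) pair. Segments lacking
#' lipids from either layer are skipped. With this normalization a layer is
#' perfectly correlated with a copy of itself (ratio exactly 1).
#'
#' A symmetric Pearson alternative (`method = "pearson"`), the correlation of
#' segment-mean tilts between the two layers, is offered for comparison; it
#' is not the reference definition.
#'
#' @param directors A director tibble from [compute_directors()] (must carry
#'   the `box` attribute), or a list of such tibbles, one per trajectory
#'   frame.
#' @param l1,l2 Layer indices (0-based).
#' @param segments Lateral segments per direction; default 50.
#' @param method `"ratio"` (default, the reference definition) or
#'   `"pearson"`.
#' @return A one-row tibble: `correlation`, `l1`, `l2`, `segments`,
#'   `n_segments_used`, `method`.
#' @examples
#' cfg <- simulate_multilayer(n_layers = 2, lipids_per_layer = 400,
#'                            amplitude = 20, wavelength = 80, seed = 1)
#' d <- compute_directors(cfg)
#' interlayer_tilt_correlation(d, 0, 1, segments = 10)
#' @export
interlayer_tilt_correlation <- function(directors, l1, l2, segments = 50,
                                        method = c("ratio", "pearson")) {
  method <- match.arg(method)
  frames <- if (is.data.frame(directors)) list(directors) else directors
  if (segments < 1) {
    rlang::abort("segments must be >= 1",
                 class = "lamellaflex_invalid_parameter")
  }
  num_sum <- 0; num_n <- 0
  den_sum <- 0; den_n <- 0
  seg_used <- 0
  seg_means <- list(a = numeric(0), b = numeric(0))
  for (fr in frames) {
    box <- attr(fr, "box")
    if (is.null(box)) {
      rlang::abort("directors must carry a box attribute for segmentation",
                   class = "lamellaflex_invalid_parameter")
    }
    a <- fr[fr$layer_index == l1, ]
    b <- fr[fr$layer_index == l2, ]
    if (nrow(a) == 0 || nrow(b) == 0) {
      rlang::abort("both layers must be present",
                   class = "lamellaflex_invalid_parameter")
    }
    seg_of <- function(d) {
      ix <- floor(d$x / box[1] * segments) %% segments
      iy <- floor(d$y / box[2] * segments) %% segments
      ix * segments + iy
    }
    sa <- split(a$tilt_deg, seg_of(a))
    sb <- split(b$tilt_deg, seg_of(b))
    shared <- intersect(names(sa), names(sb))
    for (s in shared) {
      ta <- sa[[s]]; tb <- sb[[s]]
      num_sum <- num_sum + sum(ta) * sum(tb)
      num_n <- num_n + length(ta) * length(tb)
      den_sum <- den_sum + sum(ta)^2
      den_n <- den_n + length(ta)^2
      seg_means$a <- c(seg_means$a, mean(ta))
      seg_means$b <- c(seg_means$b, mean(tb))
      seg_used <- seg_used + 1
    }
  }
  if (seg_used == 0) {
    rlang::abort("no segment contains lipids from both layers",
                 class = "lamellaflex_invalid_parameter")
  }
  corr <- if (method == "ratio") {
    den <- den_sum / den_n
    if (den <= 0) {
      rlang::abort("undefined correlation: all reference-layer tilts are zero",
                   class = "lamellaflex_undefined_correlation")
    }
    (num_sum / num_n) / den
  } else {
    if (seg_used < 2) {
      rlang::abort("pearson method needs at least two shared segments",
                   class = "lamellaflex_invalid_parameter")
    }
    stats::cor(seg_means$a, seg_means$b)
  }
  tibble::tibble(correlation = corr, l1 = l1, l2 = l2,
                 segments = segments, n_segments_used = seg_used,
                 method = method)
}
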