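#' Field-transfer specification
#'
#' Controls the Gaussian sampling-and-weighting map used to carry per-element
#' fields from the previous mesh onto a freshly built one.
#'
#' @param sigma Gaussian kernel width in mm. Defaults, when used through the
#'   simulation driver, to one callus element size.
#' @param samples_per_element Sample points taken in each source element:
#'   1 = centroid, 4 = 2x2 Gauss points.
#' @return An object of class `field_transfer_spec`.
#' @export
field_transfer_spec <- function(sigma = 0.25, samples_per_element = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  if (!samples_per_element %in% c(1, 4))
    stop("samples_per_element must be 1 (centroid) or 4 (2x2 Gauss)")
  structure(list(sigma = sigma, samples_per_element = samples_per_element),
            class = "field_transfer_spec")
}

# Internal: sparse-ish weight matrix mapping old element values to new
# element values, built region by region. Rows sum to 1. An exact
# coordinate hit short-circuits to that sample (sigma -> 0 consistency), so
# unchanged parts of the mesh pass fields through identically.
.transfer_weights <- function(old_mesh, new_mesh, spec, skip = NULL) {
  n_new <- nrow(new_mesh$elem)
  W <- matrix(0, n_new, nrow(old_mesh$elem))
  fell_back <- FALSE
  for (reg in unique(new_mesh$region)) {
    ni <- which(new_mesh$region == reg & !(seq_len(n_new) %in% skip))
    oi <- which(old_mesh$region == reg)
    if (!length(ni)) next
    if (!length(oi)) stop("no source elements for region '", reg, "'")
    if (spec$samples_per_element == 1) {
      sp <- old_mesh$centroids[oi, , drop = FALSE]
      sp_elem <- oi
    } else {
      gp <- .element_gauss_points(old_mesh)
      rows <- as.vector(t(outer(oi, 1:4, function(e, k) (e - 1) * 4 + k)))
      sp <- gp[rows, , drop = FALSE]
      sp_elem <- rep(oi, each = 4)
    }
    q <- new_mesh$centroids[ni, , drop = FALSE]
    d2 <- outer(q[, 1], sp[, 1], "-")^2 + outer(q[, 2], sp[, 2], "-")^2
    w <- exp(-d2 / (2 * spec$sigma^2))
    w[d2 > (3 * spec$sigma)^2] <- 0
    exact <- d2 < 1e-18
    has_exact <- rowSums(exact) > 0
    w[has_exact, ] <- 0
    w[exact] <- 1
    none <- rowSums(w) == 0
    if (any(none)) {
      fell_back <- TRUE
      nearest <- apply(d2[none, , drop = FALSE], 1, which.min)
      w[cbind(which(none), nearest)] <- 1
    }
    w <- w / rowSums(w)
    # accumulate per source element
    for (k in seq_len(spec$samples_per_element)) {
      idx <- seq(k, by = spec$samples_per_element, length.out = length(oi))
      W[ni, sp_elem[idx]] <- W[ni, sp_elem[idx]] + w[, idx, drop = FALSE]
    }
  }
  if (fell_back)
    warning("some target elements had no source sample within 3*sigma; ",
            "nearest-sample fallback used")
  W
}

#' Transfer per-element fields onto a new mesh
#'
#' Each new element receives the Gaussian-distance-weighted average of the
#' old elements' values (sampled at centroids or Gauss points), region by
#' region, so tissue state never bleeds between callus, cortex and marrow.
#'
#' Three readings of the freshly distracted volume are supported. The
#' default, `new_volume = "center"`, inserts the new, undifferentiated
#' matrix at mid-gap: the lower half of the old callus keeps its position,
#' the upper half rides up with the moving fragment, and the slab in
#' between is initialised from `fresh_values`. This is where regenerating
#' tissue actually appears -- the fibrous interzone sits mid-gap with
#' mineralisation fronts advancing from both fragment ends.
#' `new_volume = "stretch"` treats the increment as a homogeneous stretch
#' of the regenerate: new callus coordinates are mapped back onto the old
#' gap (`z -> z * g_old / g_new`) before weighting, so the tissue pattern
#' dilates with the gap and both fragment ends keep their fronts -- the
#' configuration regenerating tissue actually takes, since distraction
#' strains the whole interzone rather than opening a void at one end. The
#' added volume is new, undifferentiated matrix deposited throughout the
#' interzone, so mapped callus fields are simultaneously diluted towards
#' their `fresh_values` by the volume ratio `g_old / g_new`. With
#' `new_volume = "slab"`, old callus tissue keeps all its coordinates and
#' the volume above the old gap is initialised from `fresh_values`
#' (connective tissue with no perfusion).
#'
#' Weights form a partition of unity, so constant fields are preserved
#' exactly and transferred values never leave the convex hull of the source
#' values. A new element with no source sample within `3 * sigma` falls back
#' to its nearest sample, with a warning.
#'
#' @param old_mesh,new_mesh `do_mesh` objects; `new_mesh` typically comes
#'   from [remesh()].
#' @param old_fields A data.frame (or named list of numeric vectors), one
#'   value per old element.
#' @param spec A [field_transfer_spec()].
#' @param fresh_values Named list of values for freshly distracted callus
#'   elements; fields not named default to 0.
#' @return A data.frame of transferred fields, one row per new element.
#' @export
transfer_fields <- function(old_mesh, old_fields, new_mesh,
                            spec = field_transfer_spec(),
                            new_volume = c("center", "stretch", "slab"),
                            fresh_values = list(conn = 100, cart = 0,
                                                bone = 0, cort = 0,
                                                perfusion = 0)) {
  stopifnot(inherits(old_mesh, "do_mesh"), inherits(new_mesh, "do_mesh"))
  new_volume <- match.arg(new_volume)
  old_fields <- as.data.frame(old_fields)
  if (nrow(old_fields) != nrow(old_mesh$elem))
    stop("old_fields must have one row per old element")
  old_gap <- old_mesh$geometry$current_gap
  new_gap <- new_mesh$geometry$current_gap

  if (new_volume == "center") {
    # lower half anchored, upper half translated up by the increment,
    # virgin slab in between
    inc <- new_gap - old_gap
    z <- new_mesh$centroids[, "z"]
    cal <- new_mesh$region == "callus"
    lower <- cal & z < old_gap / 2
    upper <- cal & z > old_gap / 2 + inc
    fresh <- cal & !lower & !upper
    qmesh <- new_mesh
    zq <- z
    zq[upper] <- zq[upper] - inc
    zq[!cal & z >= new_gap] <- z[!cal & z >= new_gap] - inc
    qmesh$centroids[, "z"] <- zq
    W <- .transfer_weights(old_mesh, qmesh, spec, skip = which(fresh))
    out <- as.data.frame(W %*% as.matrix(old_fields))
    names(out) <- names(old_fields)
    if (any(fresh)) {
      for (nm in names(out))
        out[[nm]][fresh] <- if (!is.null(fresh_values[[nm]]))
          fresh_values[[nm]] else 0
    }
  } else if (new_volume == "stretch") {
    # pull new centroids back into the old configuration: callus scales with
    # the gap, the top fragment translates down by the increment
    qmesh <- new_mesh
    z <- qmesh$centroids[, "z"]
    in_gap <- z > 0 & z < new_gap
    above <- z >= new_gap
    z[in_gap] <- z[in_gap] * old_gap / new_gap
    z[above] <- z[above] - (new_gap - old_gap)
    qmesh$centroids[, "z"] <- z
    W <- .transfer_weights(old_mesh, qmesh, spec)
    out <- as.data.frame(W %*% as.matrix(old_fields))
    names(out) <- names(old_fields)
    if (new_gap > old_gap) {
      dil <- old_gap / new_gap
      cal <- new_mesh$region == "callus"
      for (nm in names(out)) {
        fv <- if (!is.null(fresh_values[[nm]])) fresh_values[[nm]] else 0
        out[[nm]][cal] <- out[[nm]][cal] * dil + fv * (1 - dil)
      }
    }
  } else {
    fresh <- new_mesh$region == "callus" &
      new_mesh$centroids[, "z"] > old_gap - 1e-9
    W <- .transfer_weights(old_mesh, new_mesh, spec, skip = which(fresh))
    out <- as.data.frame(W %*% as.matrix(old_fields))
    names(out) <- names(old_fields)
    if (any(fresh)) {
      for (nm in names(out))
        out[[nm]][fresh] <- if (!is.null(fresh_values[[nm]]))
          fresh_values[[nm]] else 0
    }
  }
  rownames(out) <- NULL
  out
}
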