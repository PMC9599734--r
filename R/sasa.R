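#' Van der Waals radii used for solvent accessibility
#'
#' Shipped element-radius table (ångström). Configurable by passing a modified
#' copy to [shrake_rupley()].
#'
#' @return named numeric vector of radii.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, MG = 1.73, F = 1.47,
    AL = 1.84, V = 2.00, BE = 1.53, MN = 1.61, CA = 2.31, K = 2.75,
    NA_ = 2.27, CL = 1.75, FE = 1.52, ZN = 1.39)
}

# theoretical maximum accessible surface areas per residue type (Gly-X-Gly
# based, whole-residue), Tien et al. 2013
max_asa_table <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
    GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
    MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
    TYR = 263, VAL = 174)
}

# deterministic golden-spiral spherical quadrature: n approximately uniform
# unit vectors
golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by test-point counting: each atom's sphere of radius
#' (vdW radius + probe) is sampled with a deterministic golden-spiral
#' quadrature of `n_points` points; a point is exposed iff it lies strictly
#' outside every other atom's expanded sphere, and the atom's area is
#' (exposed / n_points) x 4 pi (r + probe)^2. The quadrature is deterministic,
#' so repeated runs are bit-identical at fixed `n_points` — no random seed is
#' involved.
#'
#' @param model a `ploop_structure`, or a data frame of atoms with columns
#'   `elesy`, `x`, `y`, `z`.
#' @param n_points test points per atom (default 960; at least 100).
#' @param probe solvent probe radius, ångström (default 1.4, a water).
#' @param radii named radius table, see [vdw_radii()].
#' @param subset optional logical/integer index: compute areas only for these
#'   atoms (all atoms still occlude).
#' @return numeric vector of areas in square ångström (length = number of
#'   atoms in `subset`, default all).
#' @export
#' @examples
#' one_c <- data.frame(elesy = "C", x = 0, y = 0, z = 0)
#' shrake_rupley(one_c)             # ~ 4*pi*(1.7+1.4)^2
shrake_rupley <- function(model, n_points = 960, probe = 1.4,
                          radii = vdw_radii(), subset = NULL) {
  atoms <- if (inherits(model, "ploop_structure")) model$atoms else model
  stopifnot(n_points >= 100)
  el <- toupper(atoms$elesy)
  el[el == "NA"] <- "NA_"
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown)) stop("no vdW radius for element(s): ",
                            paste(unknown, collapse = ", "))
  r <- unname(radii[el]) + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- golden_spiral(n_points)
  idx <- if (is.null(subset)) seq_len(n) else seq_len(n)[subset]
  out <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    # neighbours whose expanded spheres can reach atom i's surface
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
    if (!length(nb)) {
      out[k] <- 4 * pi * r[i]^2
      next
    }
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")     # n_points x 3 surface points
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- colSums((t(p[exposed, , drop = FALSE]) - xyz[j, ])^2)
      exposed[exposed] <- dj2 > r[j]^2
    }
    out[k] <- sum(exposed) / n_points * 4 * pi * r[i]^2
  }
  out
}

#' Relative solvent accessibility of a residue
#'
#' Heavy-atom SASA of the residue inside the full model, divided by the
#' residue type's theoretical maximum accessibility (whole-residue
#' normalisation), as a percentage. A Walker B aspartate under 6% is buried —
#' the regime in which short hydrogen bonds form readily.
#'
#' @param model a `ploop_structure`.
#' @param chain,resno,insert residue identity (author numbering).
#' @param n_points,probe,radii passed to [shrake_rupley()].
#' @param reference named vector of per-residue-type maxima, square ångström.
#' @return list with `residue_sasa` (square ångström), `reference_max`,
#'   `relative` (percent; may exceed 100 for unusual conformers, flagged by
#'   `over_reference`).
#' @export
relative_sasa <- function(model, chain, resno, insert = "", n_points = 960,
                          probe = 1.4, radii = vdw_radii(),
                          reference = max_asa_table()) {
  atoms <- model$atoms
  sel <- atoms$chain == chain & atoms$resno == resno & atoms$insert == insert
  if (!any(sel)) stop("residue not found: ", chain, "/", resno, insert)
  rtype <- atoms$resid[sel][1]
  if (!rtype %in% names(reference)) {
    stop("no reference maximum accessibility for residue type ", rtype)
  }
  area <- sum(shrake_rupley(atoms, n_points = n_points, probe = probe,
                            radii = radii, subset = which(sel)))
  rel <- area / reference[[rtype]] * 100
  list(residue_sasa = area, reference_max = reference[[rtype]],
       relative = rel, over_reference = rel > 100)
}
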