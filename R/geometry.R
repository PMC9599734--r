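# ---- low-level helpers -----------------------------------------------------

axyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])

dist_pt <- function(p, q) sqrt(sum((p - q)^2))

# distances from one point to every row of a coordinate matrix
dist_to <- function(p, m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 3)
  sqrt(colSums((t(m) - p)^2))
}

angle_deg <- function(a, center, b) {
  u <- a - center; v <- b - center
  cv <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cv))) * 180 / pi
}

res_atoms <- function(model, chain, resno, insert = "") {
  a <- model$atoms
  a[a$chain == chain & a$resno == resno & a$insert == insert, , drop = FALSE]
}

res_label <- function(r) sprintf("%s/%s%d%s", r$chain[1], r$resid[1], r$resno[1],
                                 r$insert[1])

# ---- diagnostic distances --------------------------------------------------

#' Walker B to K+1 hydrogen-bond length
#'
#' Minimum distance from the Walker B carboxylate oxygens (OD1/OD2 for Asp,
#' OE1/OE2 for Glu) to the \[Ser/Thr\]K+1 hydroxyl oxygen (OG/OG1). This is
#' the diagnostic distance of the survey: it is systematically shorter in
#' transition-state-like structures. Reported at 0.01 ångström precision; use
#' `round(d, 1)` when comparing against values printed at 0.1 ångström.
#'
#' @param annotation a `ploop_annotation` (see [annotate_site()]).
#' @return distance in ångström, or `NA` if either partner or its atoms are
#'   missing.
#' @export
wb_k1_distance <- function(annotation) {
  wb <- annotation$wb_residue; k1 <- annotation$k_plus_1
  if (is.null(wb) || is.null(k1)) return(NA_real_)
  cox <- wb[wb$elety %in% c("OD1", "OD2", "OE1", "OE2"), , drop = FALSE]
  hyd <- k1[k1$elety %in% c("OG", "OG1"), , drop = FALSE]
  if (nrow(cox) == 0L || nrow(hyd) == 0L) return(NA_real_)
  round(min(dist_to(as.numeric(axyz(hyd)[1, ]), axyz(cox))), 2)
}

#' Distance from the K-3 backbone amide to the nearest gamma-phosphate oxygen
#'
#' Heavy-atom proxy (N to O/F) for the HN(K-3) hydrogen bond that contacts
#' O2G in transition-state-like structures. When the gamma-phosphate is
#' replaced by a mimic, its fluorines/oxygens stand in for the gamma oxygens.
#'
#' @param annotation a `ploop_annotation`.
#' @param site a `ploop_site`.
#' @return distance in ångström or `NA` when there is no gamma moiety or no
#'   K-3 backbone nitrogen.
#' @export
hnk3_gamma_distance <- function(annotation, site) {
  k3 <- annotation$k_minus_3
  if (is.null(k3)) return(NA_real_)
  n <- k3[k3$elety == "N", , drop = FALSE]
  go <- gamma_peripheral_atoms(site)
  if (nrow(n) == 0L || is.null(go) || nrow(go) == 0L) return(NA_real_)
  round(min(dist_to(as.numeric(axyz(n)[1, ]), axyz(go))), 2)
}

# peripheral O/F atoms of the gamma-phosphate or its mimic
gamma_peripheral_atoms <- function(site) {
  if (!is.null(site$ligand$mimic)) {
    m <- site$ligand$mimic$atoms
    m[m$elesy %in% c("F", "O"), , drop = FALSE]
  } else if ("PG" %in% site$ligand$atoms$elety) {
    l <- site$ligand$atoms
    l[l$elety %in% c("O1G", "O2G", "O3G", "S1G"), , drop = FALSE]
  } else NULL
}

# central atom (PG for intact NTP, Al/Be/Mg/V/P for mimics)
gamma_center_atom <- function(site) {
  if (!is.null(site$ligand$mimic)) {
    site$ligand$mimic$center
  } else {
    l <- site$ligand$atoms
    pg <- l[l$elety == "PG", , drop = FALSE]
    if (nrow(pg)) pg[1, , drop = FALSE] else NULL
  }
}

# ---- Mg coordination shell -------------------------------------------------

#' Resolve the octahedral Mg2+ coordination shell
#'
#' Takes the six nearest O/N atoms within the shell cutoff (default 2.6
#' ångström) of the cofactor ion and assigns the canonical ligand numbers:
#' #1 = O2B of beta-phosphate, #2 = O1G of gamma-phosphate (or the mimic atom
#' standing in for it), #4 = the \[Ser/Thr\]K+1 hydroxyl. The assignment of #4
#' is confirmed by it being trans to #2 (Mg-centred angle closest to 180
#' degrees). Of the remaining ligands, the one trans to #1 is #6 and the last
#' trans pair is split so that #3 is the member nearer the Walker B
#' carboxylate (the proton entry side) and #5 the other; this convention
#' reproduces the canonical shell connectivity and is configurable only in the
#' sense that labels #3/#5/#6 are descriptive, not load-bearing for QC.
#' Shell edges are all ligand-ligand pairs that are cis (Mg-centred angle
#' < 120 degrees), i.e. the 12 edges of an ideal octahedron.
#'
#' @param site a `ploop_site` with a cofactor ion.
#' @param model the owning `ploop_structure`.
#' @param annotation optional `ploop_annotation`, used to pin #4 to the K+1
#'   hydroxyl and to orient the #3/#5 split; without it the labels fall back to
#'   pure geometry.
#' @param config a [ploop_config()].
#' @return An object of class `ploop_shell`: list with `ion` (atom row),
#'   `ligands` (data frame of shell atoms with a `pos` label column),
#'   `edges` (numeric vector of cis ligand-ligand distances), `complete`
#'   (exactly six ligands found).
#' @export
mg_coordination_shell <- function(site, model, annotation = NULL,
                                  config = ploop_config()) {
  ion <- site$ion
  if (is.null(ion)) stop("site has no cofactor ion")
  p0 <- as.numeric(axyz(ion)[1, ])
  a <- model$atoms
  cand <- a[a$elesy %in% c("O", "N", "F") &
              !(a$chain == ion$chain[1] & a$resno == ion$resno[1] &
                  a$insert == ion$insert[1]), , drop = FALSE]
  d <- dist_to(p0, axyz(cand))
  keep <- d <= config$shell
  cand <- cand[keep, , drop = FALSE]
  d <- d[keep]
  ord <- order(d, cand$chain, cand$resno, cand$elety)
  cand <- cand[ord, , drop = FALSE]
  d <- d[ord]
  if (nrow(cand) > 6L) { cand <- cand[1:6, , drop = FALSE]; d <- d[1:6] }
  n <- nrow(cand)

  pos <- rep(NA_character_, n)
  lig <- site$ligand$atoms
  is_lig_atom <- function(i, name) {
    cand$elety[i] == name &&
      any(lig$chain == cand$chain[i] & lig$resno == cand$resno[i] &
            lig$elety == name)
  }
  for (i in seq_len(n)) if (is_lig_atom(i, "O2B")) { pos[i] <- "1"; break }
  # #2: O1G of an intact gamma-phosphate, else the mimic atom in the shell
  i2 <- NA_integer_
  for (i in seq_len(n)) if (is_lig_atom(i, "O1G")) { i2 <- i; break }
  if (is.na(i2) && !is.null(site$ligand$mimic)) {
    mm <- site$ligand$mimic$atoms
    for (i in seq_len(n)) {
      if (any(mm$chain == cand$chain[i] & mm$resno == cand$resno[i] &
                mm$elety == cand$elety[i])) { i2 <- i; break }
    }
  }
  if (!is.na(i2)) pos[i2] <- "2"
  # #4: K+1 hydroxyl when annotated, else the ligand trans to #2
  xyz <- axyz(cand)
  if (!is.null(annotation) && !is.null(annotation$k_plus_1)) {
    k1 <- annotation$k_plus_1
    for (i in seq_len(n)) {
      if (is.na(pos[i]) && cand$elety[i] %in% c("OG", "OG1") &&
          any(k1$chain == cand$chain[i] & k1$resno == cand$resno[i]))
        pos[i] <- "4"
    }
  }
  if (!any(pos == "4", na.rm = TRUE) && !is.na(i2)) {
    free <- which(is.na(pos))
    if (length(free)) {
      ang <- vapply(free, function(i)
        angle_deg(as.numeric(xyz[i, ]), p0, as.numeric(xyz[i2, ])), numeric(1))
      pos[free[which.max(ang)]] <- "4"
    }
  }
  # #6 trans to #1; remaining trans pair -> #3 (nearer Walker B) / #5
  i1 <- which(pos == "1")
  free <- which(is.na(pos))
  if (length(i1) == 1L && length(free)) {
    ang <- vapply(free, function(i)
      angle_deg(as.numeric(xyz[i, ]), p0, as.numeric(xyz[i1, ])), numeric(1))
    pos[free[which.max(ang)]] <- "6"
  }
  free <- which(is.na(pos))
  if (length(free)) {
    wbp <- NULL
    if (!is.null(annotation) && !is.null(annotation$wb_residue)) {
      wb <- annotation$wb_residue
      co <- wb[wb$elety %in% c("OD1", "OD2", "OE1", "OE2"), , drop = FALSE]
      if (nrow(co)) wbp <- axyz(co)
    }
    if (!is.null(wbp) && length(free) >= 1L) {
      dwb <- vapply(free, function(i) min(dist_to(as.numeric(xyz[i, ]), wbp)),
                    numeric(1))
      pos[free[order(dwb)]] <- c("3", "5", "7", "8")[seq_along(free)]
    } else {
      pos[free] <- c("3", "5", "7", "8")[seq_along(free)]
    }
  }
  cand$pos <- pos
  cand$mg_dist <- d

  edges <- numeric(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (angle_deg(as.numeric(xyz[i, ]), p0, as.numeric(xyz[j, ])) < 120) {
        edges <- c(edges, dist_pt(as.numeric(xyz[i, ]), as.numeric(xyz[j, ])))
      }
    }
  }
  structure(list(ion = ion, ligands = cand, edges = edges,
                 complete = n == 6L),
            class = "ploop_shell")
}

#' @export
print.ploop_shell <- function(x, ...) {
  cat(sprintf("<ploop_shell> %d ligand(s)%s; mean Mg-L %.2f A; %d edges, mean %.3f A\n",
              nrow(x$ligands), if (x$complete) " (complete octahedron)" else "",
              mean(x$ligands$mg_dist), length(x$edges),
              if (length(x$edges)) mean(x$edges) else NA_real_))
  print(x$ligands[, c("pos", "chain", "resno", "resid", "elety", "mg_dist")],
        row.names = FALSE)
  invisible(x)
}

# ---- H-bond classification and pKa calibration -----------------------------

#' Classify a hydrogen bond by donor-acceptor distance
#'
#' Short H-bonds are those under 2.7 ångström; 2.7–3.2 ångström is the typical
#' range; anything longer is classed long. Boundary values fall into the
#' typical class.
#'
#' @param d donor-acceptor heavy-atom distance(s), ångström; must be positive.
#' @return character vector, `"short"`, `"typical"` or `"long"`.
#' @export
#' @examples
#' classify_hbond(c(2.5, 2.7, 2.9, 3.3))
classify_hbond <- function(d) {
  if (any(!is.na(d) & d <= 0)) stop("distances must be positive")
  ifelse(is.na(d), NA_character_,
         ifelse(d < 2.7, "short", ifelse(d <= 3.2, "typical", "long")))
}

#' Estimate the donor/acceptor pKa mismatch from an O-H...O bond length
#'
#' Linear calibration through the two empirical anchor points (2.4 ångström, 0
#' pKa units) and (2.9 ångström, 20 pKa units), clamped to \[0, 20\] outside
#' that interval: the pKa difference that an O-H...O bridge of a given length
#' can sustain shrinks to zero as the bond contracts to the low-barrier
#' regime.
#'
#' @param d O...O distance(s), ångström; positive.
#' @return numeric vector of pKa-unit estimates in \[0, 20\].
#' @export
#' @examples
#' delta_pka_estimate(c(2.4, 2.65, 2.9))
delta_pka_estimate <- function(d) {
  stopifnot(all(is.na(d) | d > 0))
  pmin(20, pmax(0, (d - 2.4) / (2.9 - 2.4) * 20))
}

# ---- superposition ---------------------------------------------------------

# Kabsch least-squares rigid superposition of x onto y (n x 3 matrices)
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  dsign <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  xr <- xc %*% t(r)
  list(rotation = r, translation = as.numeric(cy - cx %*% t(r)),
       rmsd = sqrt(mean(rowSums((xr - yc)^2))),
       center_mobile = cx, center_ref = cy)
}

#' Superpose the P-loop region of two annotated structures
#'
#' Least-squares (Kabsch) rigid-body superposition on the backbone N/CA/C/O
#' atoms of the 20-residue window K-12 .. K+7 around the Walker A lysine —
#' the beta1-strand, P-loop and alpha1-helix stretch that is structurally
#' conserved across the superfamily.
#'
#' @param mobile,reference lists with elements `model` (`ploop_structure`) and
#'   `annotation` (`ploop_annotation`).
#' @return list with `rotation` (3x3), `translation` (length 3; the transform
#'   maps mobile coordinates onto the reference frame), and `rmsd` in
#'   ångström.
#' @export
superpose_ploop <- function(mobile, reference) {
  grab <- function(s) {
    lw <- s$annotation$lys_wa
    if (is.null(lw)) stop("structure is not annotated (no Walker A lysine)")
    ch <- lw$chain[1]; k <- lw$resno[1]
    want <- (k - 12L):(k + 7L)
    m <- NULL
    missing <- character(0)
    for (r in want) {
      ra <- res_atoms(s$model, ch, r)
      bb <- ra[match(c("N", "CA", "C", "O"), ra$elety), , drop = FALSE]
      if (any(is.na(bb$elety))) {
        missing <- c(missing, sprintf("%s/%d", ch, r))
      } else m <- rbind(m, axyz(bb))
    }
    if (length(missing)) stop("P-loop window incomplete, missing backbone for: ",
                              paste(missing, collapse = ", "))
    m
  }
  xm <- grab(mobile); xr <- grab(reference)
  k <- kabsch(xm, xr)
  k[c("rotation", "translation", "rmsd")]
}

# ---- contact inventory and post-hydrolysis distance ------------------------

#' Inventory of polar contacts around the gamma-moiety and catalytic water
#'
#' All donor/acceptor heavy-atom pairs between the gamma-phosphate or its
#' mimic (plus the catalytic water when present) and protein N/O atoms within
#' the polar-contact radius (3.6 ångström). Contacts at or under 3.2 ångström
#' are labelled `moderate`, longer ones `weak`; these strength labels follow
#' standard H-bond taxonomy.
#'
#' @param site a `ploop_site`.
#' @param annotation a `ploop_annotation` (for the catalytic water).
#' @param model the `ploop_structure`.
#' @param config a [ploop_config()].
#' @return data frame: `from_atom`, `residue`, `atom`, `distance`, `strength`,
#'   sorted by distance; zero rows when nothing is in range.
#' @export
contact_inventory <- function(site, annotation, model, config = ploop_config()) {
  src <- gamma_peripheral_atoms(site)
  ctr <- gamma_center_atom(site)
  if (!is.null(ctr)) src <- rbind(src, ctr)
  if (!is.null(annotation$wcat)) {
    src <- rbind(src, annotation$wcat[annotation$wcat$elety == "O", , drop = FALSE])
  }
  a <- model$atoms
  prot <- a[!a$het & a$elesy %in% c("N", "O") & a$resid %in% aa3(), , drop = FALSE]
  out <- NULL
  if (!is.null(src) && nrow(src) && nrow(prot)) {
    pm <- axyz(prot)
    for (i in seq_len(nrow(src))) {
      d <- dist_to(as.numeric(axyz(src)[i, ]), pm)
      hit <- which(d <= config$polar_contact)
      if (length(hit)) {
        out <- rbind(out, data.frame(
          from_atom = src$elety[i],
          residue = sprintf("%s/%s%d%s", prot$chain[hit], prot$resid[hit],
                            prot$resno[hit], prot$insert[hit]),
          atom = prot$elety[hit],
          distance = round(d[hit], 2),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(from_atom = character(0), residue = character(0),
                      atom = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out$strength <- ifelse(out$distance <= config$hbond_moderate, "moderate", "weak")
  out[order(out$distance), , drop = FALSE]
}

#' Distance between beta-phosphate and a detached inorganic phosphate
#'
#' Minimum O(beta-phosphate) to O(Pi) distance in post-hydrolysis sites (NDP
#' plus a separate phosphate). Values within H-bond range (2.4-2.5 ångström in
#' the reference structures) indicate the charge-compensating contact formed
#' after gamma-phosphate detachment; larger values are still reported but
#' flagged non-bonding.
#'
#' @param site a `ploop_site` with an NDP ligand.
#' @param model the `ploop_structure` (searched for `PO4`/`PI` residues; the
#'   one nearest the beta-phosphate is used, whether or not it was close
#'   enough to be associated with the ligand).
#' @param config a [ploop_config()].
#' @return list with `distance` (ångström or `NA` when no phosphate residue is
#'   present) and `bonding` (logical, distance at or under the polar-contact
#'   radius).
#' @export
beta_pi_distance <- function(site, model, config = ploop_config()) {
  lig <- site$ligand$atoms
  bo <- lig[lig$elety %in% c("O1B", "O2B", "O3B"), , drop = FALSE]
  a <- model$atoms
  po <- a[a$het & a$resid %in% c("PO4", "PI") & a$elesy == "O", , drop = FALSE]
  if (nrow(bo) == 0L || nrow(po) == 0L) {
    return(list(distance = NA_real_, bonding = NA))
  }
  d <- min(apply(axyz(bo), 1, function(p) min(dist_to(p, axyz(po)))))
  list(distance = round(d, 2), bonding = d <= config$polar_contact)
}
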