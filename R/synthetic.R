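# ---- blueprint -------------------------------------------------------------

#' Blueprint for a synthetic catalytic site
#'
#' Fully determines (together with `seed`) an idealised P-loop catalytic site:
#' a Mg2+ ion at the origin with an octahedral oxygen shell at
#' `mg_bond_length` on the axes (#1 = O2B, #2 = O1G or its mimic stand-in,
#' #4 = the K+1 hydroxyl, #3/#5/#6 waters or the Switch I hydroxyl), an
#' extended di/tri-phosphate with IUPAC atom names, a P-loop-like backbone
#' (20-residue window K-12..K+7, author numbering 217-236 with the Walker A
#' lysine at 229), a Walker B aspartate at 270 whose nearest carboxylate
#' oxygen is exactly `wb_k1_target` from the K+1 hydroxyl oxygen and whose
#' three preceding residues are `wb_window`, an optional apical catalytic
#' water and optional Switch I threonine, plus Gaussian coordinate jitter.
#' The peptide geometry is minimal-but-legal (standard bond lengths, no
#' Ramachandran realism): the pipeline consumes distances and angles, not
#' stereochemistry.
#'
#' @param mg_bond_length Mg-O shell bond length, ångström (default 2.1).
#' @param wb_k1_target planted Walker-B-to-K+1 O...O distance (default 2.6).
#' @param wb_window names of the three residues preceding the Walker B Asp
#'   (default Leu-Ile-Val; put an ionizable name here to exercise the fallback
#'   rule).
#' @param gamma_moiety `"PO3"` (intact NTP), `"ALF4"`, `"ALF3"`, `"MGF3"`,
#'   `"BEF3"`, `"VO4"`, `"Pi"` (detached phosphate, post-hydrolysis) or
#'   `"none"` (bare NDP).
#' @param base `"A"` or `"G"` nucleotide family.
#' @param k1_residue `"THR"`, `"SER"` or `"GLY"` (kinase-like exception).
#' @param k3_residue residue name at K-3 (default `"ASN"`).
#' @param include_wcat place the apical catalytic water.
#' @param wcat_angle,wcat_dist planted O3B-X-Ow angle (degrees) and X-Ow
#'   distance of that water.
#' @param include_switch_i place a Switch I threonine whose OG1 is shell
#'   ligand #3 (otherwise a water W3 sits there).
#' @param include_ion place the Mg2+ ion.
#' @param hnk3_target planted K-3 backbone-N to O2G distance (default 3.0).
#' @param lys_nz_dist planted Lys NZ to O1B distance (default 3.0).
#' @param pi_beta_target planted O(beta)-O(Pi) distance for `"Pi"` sites.
#' @param wb_decoy_dist if not `NA`, adds a decoy Asp (resno 280, with a Ser
#'   in its preceding window) whose carboxylate O is this far from the K+1
#'   hydroxyl.
#' @param cat_carboxylate_dist if not `NA`, adds a Glu (resno 290) with OE1
#'   this far from the catalytic water.
#' @param jitter_sd Gaussian coordinate noise, ångström (default 0).
#' @param seed RNG seed used for the jitter.
#' @return list of class `site_blueprint`.
#' @export
site_blueprint <- function(mg_bond_length = 2.1, wb_k1_target = 2.6,
                           wb_window = c("LEU", "ILE", "VAL"),
                           gamma_moiety = "PO3", base = "A",
                           k1_residue = "THR", k3_residue = "ASN",
                           include_wcat = TRUE, wcat_angle = 170,
                           wcat_dist = 3.2, include_switch_i = FALSE,
                           include_ion = TRUE, hnk3_target = 3.0,
                           lys_nz_dist = 3.0, pi_beta_target = 2.45,
                           wb_decoy_dist = NA_real_,
                           cat_carboxylate_dist = NA_real_,
                           jitter_sd = 0, seed = 1L) {
  bp <- as.list(environment())
  gamma_moiety <- match.arg(gamma_moiety,
                            c("PO3", "ALF4", "ALF3", "MGF3", "BEF3", "VO4",
                              "Pi", "none"))
  stopifnot(mg_bond_length > 1, wb_k1_target >= 1.5, hnk3_target > 1,
            lys_nz_dist > 1, jitter_sd >= 0, length(wb_window) == 3)
  class(bp) <- "site_blueprint"
  bp
}

# ---- small constructors ----------------------------------------------------

vnorm <- function(v) v / sqrt(sum(v^2))

new_atoms <- function() {
  data.frame(chain = character(0), resno = integer(0), insert = character(0),
             resid = character(0), elety = character(0), elesy = character(0),
             x = numeric(0), y = numeric(0), z = numeric(0), o = numeric(0),
             alt = character(0), het = logical(0), stringsAsFactors = FALSE)
}

add_atoms <- function(df, resno, resid, elety, elesy, xyz, het = FALSE,
                      chain = "A") {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  stopifnot(ncol(xyz) == 3)
  rbind(df, data.frame(chain = chain, resno = as.integer(resno), insert = "",
                       resid = resid, elety = elety, elesy = elesy,
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1,
                       alt = "", het = het, stringsAsFactors = FALSE))
}

# phase angle placing the first ring atom of a substituent ring at distance
# `target` from the origin; ring atoms sit at X + r*(cos(phi) e1 + sin(phi) e2)
# (theta = 90 deg) or tilted by theta from the axis a1
ring_phase <- function(X, a1, e1, r, theta_deg, target) {
  th <- theta_deg * pi / 180
  xa <- sum(X * a1); xe <- sum(X * e1)
  # |X + r(cos th * a1 + sin th (cos phi e1 + sin phi e2))|^2 == target^2,
  # X has no e2 component by construction of e1
  cphi <- (target^2 - sum(X^2) - r^2 - 2 * r * cos(th) * xa) /
    (2 * r * sin(th) * xe)
  acos(max(-1, min(1, cphi)))
}

# ---- generator -------------------------------------------------------------

#' Build an idealised catalytic-site structure with ground truth
#'
#' Deterministically assembles the structure described by a [site_blueprint()]
#' and returns it together with the planted ground-truth labels, so that every
#' annotation stage can be verified against construction. Identical blueprint
#' and seed give identical output.
#'
#' @param bp a [site_blueprint()].
#' @return list with `model` (a `ploop_structure`) and `truth`: planted
#'   residue identities (`lys_wa`, `k_plus_1`, `k_minus_3`, `wb`, `switch_i`,
#'   `wcat` author numbers, all in chain A), the planted distances
#'   (`wb_k1`, `hnk3_o2g`, `k1_mg`, `shell_edge`), the pre-jitter shell
#'   position map (`shell`, data frame of pos/resno/elety), `ligand_class`
#'   and the gamma species.
#' @export
build_ideal_site <- function(bp = site_blueprint()) {
  stopifnot(inherits(bp, "site_blueprint"))
  b <- bp$mg_bond_length

  # octahedral anchors
  O2B <- c(b, 0, 0); O1G <- c(0, b, 0); OG1 <- c(0, -b, 0)
  P3 <- c(0, 0, b); P5 <- c(0, 0, -b); P6 <- c(-b, 0, 0)

  # extended triphosphate skeleton in the z = 0 plane, mirror-symmetric about
  # the x = y diagonal: PB and PG 2.98 A apart, bridging O3B equidistant
  dpq <- 2.98 / sqrt(2)
  disc <- (b + dpq)^2 - 2 * (b^2 + dpq^2 - 1.52^2)
  p <- ((b + dpq) + sqrt(disc)) / 2
  q <- p - dpq
  PB <- c(p, q, 0); PG <- c(q, p, 0)
  ssum <- p + q
  disc2 <- ssum^2 - 2 * (p^2 + q^2 - 1.645^2)
  s <- (ssum + sqrt(disc2)) / 2
  O3B <- c(s, s, 0)

  u6 <- function(a, bb, cc) vnorm(c(a, bb, cc))
  O1B <- PB + 1.49 * u6(1, -1, 2)
  O3A <- PB + 1.59 * u6(1, -1, -2)
  PA  <- O3A + 1.60 * vnorm(c(1, -0.5, -1.5))
  O1A <- PA + 1.48 * vnorm(c(-1, -1, -0.5))
  O2A <- PA + 1.48 * vnorm(c(1, 0, -1))
  O2G <- PG + 1.49 * u6(1, 1, 2)    # virtual when a mimic replaces PG
  O3G <- PG + 1.49 * u6(1, 1, -2)

  gm <- bp$gamma_moiety
  intact <- gm == "PO3"
  nuc_code <- if (intact) {
    if (bp$base == "A") "ATP" else "GTP"
  } else {
    if (bp$base == "A") "ADP" else "GDP"
  }

  atoms <- new_atoms()
  nuc <- rbind(PA, O1A, O2A, O3A, PB, O1B, O2B, O3B)
  nuc_names <- c("PA", "O1A", "O2A", "O3A", "PB", "O1B", "O2B", "O3B")
  if (intact) {
    nuc <- rbind(nuc, PG, O1G, O2G, O3G)
    nuc_names <- c(nuc_names, "PG", "O1G", "O2G", "O3G")
  }
  atoms <- add_atoms(atoms, 302L, nuc_code, nuc_names,
                     substr(nuc_names, 1, 1), nuc, het = TRUE)

  # gamma mimic centred at the PG position, apical axis along O3B -> PG
  a1 <- vnorm(PG - O3B)
  Xp <- PG - sum(PG * a1) * a1
  e1 <- -vnorm(Xp)                       # in-plane direction toward the ion
  e2 <- c(a1[2] * e1[3] - a1[3] * e1[2],
          a1[3] * e1[1] - a1[1] * e1[3],
          a1[1] * e1[2] - a1[2] * e1[1])
  ring <- function(r, theta, k, target) {
    phi <- ring_phase(PG, a1, e1, r, theta, target)
    t(vapply(phi + (seq_len(k) - 1) * 2 * pi / k, function(ps) {
      th <- theta * pi / 180
      PG + r * (cos(th) * a1 + sin(th) * (cos(ps) * e1 + sin(ps) * e2))
    }, numeric(3)))
  }
  mimic_truth <- NA_character_
  if (gm %in% c("ALF4", "ALF3", "MGF3", "BEF3")) {
    spec <- switch(gm,
                   ALF4 = list(code = "ALF", el = "AL", r = 1.69, k = 4),
                   ALF3 = list(code = "AF3", el = "AL", r = 1.63, k = 3),
                   MGF3 = list(code = "MGF", el = "MG", r = 1.83, k = 3),
                   BEF3 = list(code = "BEF", el = "BE", r = 1.55, k = 3))
    fl <- ring(spec$r, 90, spec$k, b)
    atoms <- add_atoms(atoms, 303L, spec$code,
                       c(spec$el, paste0("F", seq_len(spec$k))),
                       c(spec$el, rep("F", spec$k)),
                       rbind(PG, fl), het = TRUE)
    mimic_truth <- switch(gm, ALF4 = "AlF4", ALF3 = "AlF3", MGF3 = "MgF3",
                          BEF3 = "BeF3")
  } else if (gm == "VO4") {
    Oapi <- PG + 1.66 * a1
    Oeq <- ring(1.66, 109.47, 3, b)
    atoms <- add_atoms(atoms, 303L, "VO4", c("V", "O1", "O2", "O3", "O4"),
                       c("V", "O", "O", "O", "O"),
                       rbind(PG, Oeq, Oapi), het = TRUE)
    mimic_truth <- "VO4"
  } else if (gm == "Pi") {
    # detached inorganic phosphate H-bonded to the terminal beta-oxygen:
    # its nearest oxygen sits exactly pi_beta_target from O3B, the rest of
    # the moiety points away from the site
    O1P <- O3B + bp$pi_beta_target * a1
    PPi <- O1P + 1.52 * a1
    perp <- vnorm(c(-a1[2], a1[1], 0.4))
    perp2 <- c(a1[2] * perp[3] - a1[3] * perp[2],
               a1[3] * perp[1] - a1[1] * perp[3],
               a1[1] * perp[2] - a1[2] * perp[1])
    atoms <- add_atoms(atoms, 304L, "PO4", c("P", "O1", "O2", "O3", "O4"),
                       c("P", "O", "O", "O", "O"),
                       rbind(PPi, O1P, PPi + 1.52 * a1,
                             PPi + 1.52 * perp, PPi + 1.52 * perp2),
                       het = TRUE)
  }
  gamma_center <- PG

  # cofactor ion
  if (bp$include_ion) {
    atoms <- add_atoms(atoms, 301L, "MG", "MG", "MG", c(0, 0, 0), het = TRUE)
  }

  # ---- P-loop backbone: CA trace, then backbone atoms ----
  k <- 229L
  CA <- list()
  CA[["229"]] <- c(4.4, -1.9, 2.5)
  CA[["230"]] <- c(1.4, -(b + 1.5), 1.2)
  CA[["228"]] <- c(6.4, 0.8, 3.6)
  CA[["227"]] <- c(6.0, 4.5, 3.9)
  CA[["226"]] <- c(3.3, 7.0, 3.3)
  d1 <- vnorm(c(-0.432, 0.864, 0.259))
  for (i in 1:9) CA[[as.character(226L - i)]] <- CA[["226"]] + i * 3.8 * d1
  d2 <- vnorm(c(-0.688, -0.688, 0.206))
  for (j in 1:6) CA[[as.character(230L + j)]] <- CA[["230"]] + j * 3.8 * d2

  seqnames <- c("VAL", "ILE", "LEU", "VAL", "ALA", "ALA", "GLY", "ALA", "ALA",
                bp$k3_residue, "ALA", "GLY", "LYS", bp$k1_residue,
                "ALA", "LEU", "VAL", "ALA", "ILE", "GLY")
  names(seqnames) <- as.character(217:236)

  # Walker B strand (window 267-269, Asp 270, Gly 271)
  u_wb <- vnorm(c(0, -0.6, 1))
  OD2 <- OG1 + bp$wb_k1_target * u_wb
  CGd <- OD2 + 1.25 * vnorm(c(0.2, -0.8, 0.6))
  OD1 <- CGd + 1.25 * vnorm(c(0.5, -0.2, 0.84))
  CBd <- CGd + 1.52 * vnorm(c(0, -0.55, 0.84))
  CAd <- CBd + 1.53 * vnorm(c(-0.3, -0.7, 0.65))
  stopifnot(dist_pt(OD1, OG1) > dist_pt(OD2, OG1))
  CA[["270"]] <- CAd
  d4 <- vnorm(c(0.25, 0.9, 0.35))
  for (kk in 1:3) CA[[as.character(270L - kk)]] <- CAd - kk * 3.8 * d4
  CA[["271"]] <- CAd + 3.8 * d4
  seqnames[as.character(267:269)] <- toupper(bp$wb_window)
  seqnames["270"] <- "ASP"
  seqnames["271"] <- "GLY"

  # optional decoy Asp 280 (preceded by a Ser at 278: fails the window rule)
  if (!is.na(bp$wb_decoy_dist)) {
    OD2x <- OG1 + bp$wb_decoy_dist * vnorm(c(0.8, -0.3, 0.55))
    CGx <- OD2x + 1.25 * vnorm(c(0.6, -0.6, 0.5))
    OD1x <- CGx + 1.25 * vnorm(c(0.8, 0.2, 0.55))
    CBx <- CGx + 1.52 * vnorm(c(0.3, -0.8, 0.5))
    CAx <- CBx + 1.53 * vnorm(c(0.5, -0.6, 0.6))
    stopifnot(dist_pt(OD1x, OG1) > dist_pt(OD2x, OG1))
    CA[["280"]] <- CAx
    d4x <- vnorm(c(0.9, 0.3, 0.3))
    for (kk in 1:3) CA[[as.character(280L - kk)]] <- CAx - kk * 3.8 * d4x
    seqnames[as.character(277:280)] <- c("LEU", "SER", "VAL", "ASP")
  }

  # optional Switch I segment (250-252, Thr 251 with OG1 at shell position #3)
  if (bp$include_switch_i) {
    OGs <- P3
    CAs <- OGs + 2.39 * vnorm(c(-0.3, 0.4, 1))
    CA[["251"]] <- CAs
    d5 <- vnorm(c(1, 0.3, 0.2))
    CA[["250"]] <- CAs - 3.8 * d5
    CA[["252"]] <- CAs + 3.8 * d5
    seqnames[as.character(250:252)] <- c("GLY", "THR", "GLY")
  }

  # optional W_cat-coordinating Glu 290
  Wcat <- NULL
  if (bp$include_wcat || gm == "VO4") {
    delta <- (180 - bp$wcat_angle) * pi / 180
    Wcat <- gamma_center + bp$wcat_dist * (cos(delta) * a1 + sin(delta) * e2)
  }
  if (!is.na(bp$cat_carboxylate_dist) && !is.null(Wcat)) {
    OE1 <- Wcat + bp$cat_carboxylate_dist * vnorm(c(-0.4, 0.7, 0.6))
    CDe <- OE1 + 1.25 * vnorm(c(-0.5, 0.6, 0.62))
    OE2 <- CDe + 1.25 * vnorm(c(-0.9, 0.1, 0.42))
    CGe <- CDe + 1.52 * vnorm(c(-0.2, 0.9, 0.38))
    CAe <- CGe + 2.5 * vnorm(c(-0.3, 0.8, 0.52))
    CA[["290"]] <- CAe
    CA[["289"]] <- CAe - 3.8 * vnorm(c(-0.8, 0.4, 0.45))
    CA[["291"]] <- CAe + 3.8 * vnorm(c(-0.8, 0.4, 0.45))
    seqnames[as.character(289:291)] <- c("ALA", "GLU", "ALA")
  }

  # backbone atoms from the CA trace
  resnos <- sort(as.integer(names(CA)))
  for (r in resnos) {
    key <- as.character(r)
    prv <- CA[[as.character(r - 1L)]]
    nxt <- CA[[as.character(r + 1L)]]
    here <- CA[[key]]
    dir <- if (!is.null(prv) && !is.null(nxt)) vnorm(nxt - prv)
           else if (!is.null(nxt)) vnorm(nxt - here)
           else if (!is.null(prv)) vnorm(here - prv)
           else c(1, 0, 0)
    pp <- c(dir[2], -dir[1], 0)
    if (sqrt(sum(pp^2)) < 1e-6) pp <- c(1, 0, 0)
    pp <- vnorm(pp)
    p2 <- c(dir[2] * pp[3] - dir[3] * pp[2],
            dir[3] * pp[1] - dir[1] * pp[3],
            dir[1] * pp[2] - dir[2] * pp[1])
    N <- here - 1.235 * dir + 0.78 * pp
    C <- here + 1.235 * dir + 0.886 * pp
    O <- C + 1.23 * p2
    if (r == 226L) N <- O2G + bp$hnk3_target * vnorm(c(0.3, 1, 0.5))
    rn <- seqnames[[key]]
    atoms <- add_atoms(atoms, r, rn, c("N", "CA", "C", "O"),
                       c("N", "C", "C", "O"), rbind(N, here, C, O))
  }

  # side chains of the special residues
  NZ <- O1B + bp$lys_nz_dist * vnorm(c(0.4, 0.35, 0.55))
  ca_k <- CA[["229"]]
  sc <- vapply(c(0.28, 0.47, 0.66, 0.85), function(f) ca_k + f * (NZ - ca_k),
               numeric(3))
  atoms <- add_atoms(atoms, 229L, "LYS", c("CB", "CG", "CD", "CE", "NZ"),
                     c("C", "C", "C", "C", "N"), rbind(t(sc), NZ))
  if (bp$k1_residue %in% c("THR", "SER")) {
    oname <- if (bp$k1_residue == "THR") "OG1" else "OG"
    CBk1 <- OG1 + 1.43 * vnorm(CA[["230"]] - OG1)
    atoms <- add_atoms(atoms, 230L, bp$k1_residue, c("CB", oname),
                       c("C", "O"), rbind(CBk1, OG1))
    if (bp$k1_residue == "THR") {
      atoms <- add_atoms(atoms, 230L, "THR", "CG2", "C",
                         CBk1 + 1.52 * vnorm(c(1, -0.3, -0.8)))
    }
  }
  if (bp$k3_residue == "ASN") {
    atoms <- add_atoms(atoms, 226L, "ASN", "CB", "C",
                       CA[["226"]] + 1.53 * vnorm(c(0, 0.5, -0.9)))
  }
  atoms <- add_atoms(atoms, 270L, "ASP", c("CB", "CG", "OD1", "OD2"),
                     c("C", "C", "O", "O"), rbind(CBd, CGd, OD1, OD2))
  if (!is.na(bp$wb_decoy_dist)) {
    atoms <- add_atoms(atoms, 280L, "ASP", c("CB", "CG", "OD1", "OD2"),
                       c("C", "C", "O", "O"), rbind(CBx, CGx, OD1x, OD2x))
    OGser <- CA[["278"]] + 2.4 * vnorm(c(0.2, -0.9, 0.4))
    atoms <- add_atoms(atoms, 278L, "SER", c("CB", "OG"), c("C", "O"),
                       rbind(CA[["278"]] + 1.53 * vnorm(c(0.2, -0.9, 0.4)), OGser))
  }
  if (bp$include_switch_i) {
    CBs <- P3 + 1.43 * vnorm(CA[["251"]] - P3)
    atoms <- add_atoms(atoms, 251L, "THR", c("CB", "OG1", "CG2"),
                       c("C", "O", "C"),
                       rbind(CBs, P3, CBs + 1.52 * vnorm(c(1, 0.2, 0.3))))
  }
  if (!is.na(bp$cat_carboxylate_dist) && !is.null(Wcat)) {
    atoms <- add_atoms(atoms, 290L, "GLU", c("CB", "CG", "CD", "OE1", "OE2"),
                       c("C", "C", "C", "O", "O"),
                       rbind(CGe + 1.2 * vnorm(CAe - CGe), CGe, CDe, OE1, OE2))
  }

  # waters: shell W5/W6 (and W3 unless Switch I takes #3), apical W_cat
  wat <- rbind(if (!bp$include_switch_i) P3, P5, P6)
  wno <- c(if (!bp$include_switch_i) 401L, 402L, 403L)
  atoms <- add_atoms(atoms, wno, "HOH", "O", "O", wat, het = TRUE)
  wcat_resno <- NA_integer_
  if (bp$include_wcat && gm %in% c("PO3", "ALF4", "ALF3", "MGF3", "BEF3")) {
    atoms <- add_atoms(atoms, 410L, "HOH", "O", "O", Wcat, het = TRUE)
    wcat_resno <- 410L
  }

  # jitter
  set.seed(bp$seed)
  if (bp$jitter_sd > 0) {
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::rnorm(n, 0, bp$jitter_sd)
    atoms$y <- atoms$y + stats::rnorm(n, 0, bp$jitter_sd)
    atoms$z <- atoms$z + stats::rnorm(n, 0, bp$jitter_sd)
  }
  rownames(atoms) <- NULL

  model <- structure(list(id = paste0("SYN-", gm), resolution = 1.5,
                          atoms = atoms), class = "ploop_structure")

  per_truth <- if (intact) dist_pt(O2G, O2G + bp$hnk3_target * vnorm(c(0.3, 1, 0.5)))
  truth <- list(
    lys_wa = 229L, k_plus_1 = 230L, k_minus_3 = 226L, wb = 270L,
    switch_i = if (bp$include_switch_i) 251L else NA_integer_,
    wcat = if (gm == "VO4") NA_integer_ else wcat_resno,
    chain = "A",
    wb_k1 = bp$wb_k1_target,
    hnk3_o2g = if (intact) bp$hnk3_target else {
      ga <- atoms[atoms$resno == 303L & atoms$elesy %in% c("F", "O"), , drop = FALSE]
      n226 <- atoms[atoms$resno == 226L & atoms$elety == "N", , drop = FALSE]
      if (nrow(ga) && nrow(n226))
        min(dist_to(as.numeric(axyz(n226)[1, ]), axyz(ga))) else NA_real_
    },
    k1_mg = b, shell_edge = b * sqrt(2),
    shell = data.frame(
      pos = c("1", "2", "3", "4", "5", "6"),
      resno = c(302L,
                if (intact) 302L else 303L,
                if (bp$include_switch_i) 251L else 401L,
                230L, 402L, 403L),
      stringsAsFactors = FALSE),
    species = mimic_truth,
    ligand_class = switch(gm, PO3 = if (nuc_code %in% c("ATP", "GTP"))
                            "native" else "non_hydrolyzable",
                          ALF4 = , MGF3 = , VO4 = "ts_analog",
                          ALF3 = , BEF3 = "substrate_analog",
                          "ndp_only"))
  list(model = model, truth = truth)
}

#' Generate a batch of synthetic sites with a ground-truth table
#'
#' Writes one PDB file per site and a tab-separated truth table. Per-class
#' Walker-B-to-K+1 target distances are drawn from normal distributions
#' (defaults: transition-state analogues mean 2.5, sd 0.05; all other classes
#' mean 2.65, sd 0.08 ångström). These class-conditional distributions are
#' test scaffolding echoing the qualitative class ordering, not measured data
#' — the truth-table header says so.
#'
#' @param n_per_class sites per class.
#' @param classes subset of the four ligand classes.
#' @param out_dir output directory (created if needed).
#' @param seed master seed; every file is a deterministic function of it.
#' @param jitter_sd coordinate noise per site, ångström.
#' @param class_means,class_sds named numeric vectors overriding the
#'   per-class target distributions.
#' @return invisibly, the truth table data frame (one row per file).
#' @export
build_batch <- function(n_per_class = 10, classes = c("native",
                        "non_hydrolyzable", "substrate_analog", "ts_analog"),
                        out_dir, seed = 1L, jitter_sd = 0.05,
                        class_means = NULL, class_sds = NULL) {
  stopifnot(n_per_class >= 1)
  mu <- c(native = 2.65, non_hydrolyzable = 2.65, substrate_analog = 2.65,
          ts_analog = 2.5)
  sg <- c(native = 0.08, non_hydrolyzable = 0.08, substrate_analog = 0.08,
          ts_analog = 0.05)
  if (!is.null(class_means)) mu[names(class_means)] <- class_means
  if (!is.null(class_sds)) sg[names(class_sds)] <- class_sds
  gamma_for <- c(native = "PO3", non_hydrolyzable = "PO3",
                 substrate_analog = "BEF3", ts_analog = "ALF4")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  rows <- NULL
  for (cl in classes) {
    targets <- pmax(2.2, stats::rnorm(n_per_class, mu[[cl]], sg[[cl]]))
    seeds <- sample.int(.Machine$integer.max, n_per_class)
    for (i in seq_len(n_per_class)) {
      bp <- site_blueprint(wb_k1_target = round(targets[i], 3),
                           gamma_moiety = gamma_for[[cl]],
                           jitter_sd = jitter_sd, seed = seeds[i])
      if (cl == "non_hydrolyzable") {
        out <- build_ideal_site(bp)
        out$model$atoms$resid[out$model$atoms$resid == "ATP"] <- "ANP"
      } else out <- build_ideal_site(bp)
      fn <- sprintf("%s_%03d.pdb", cl, i)
      write_structure(out$model, file.path(out_dir, fn))
      rows <- rbind(rows, data.frame(
        file = fn, ligand_class = cl, wb_k1_target = round(targets[i], 3),
        seed = seeds[i], jitter_sd = jitter_sd, stringsAsFactors = FALSE))
    }
  }
  tt <- file.path(out_dir, "truth.tsv")
  con <- file(tt, "w")
  writeLines(paste("# synthetic ground truth; class-conditional wb_k1",
                   "distributions are test scaffolding, not measured data"), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(rows)
}
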