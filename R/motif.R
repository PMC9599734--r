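# residues of one chain ordered by author numbering; returns data frame of
# (resno, insert, resid) keys
chain_residues <- function(model, chain) {
  a <- model$atoms
  a <- a[a$chain == chain & !a$het & a$resid %in% aa3(), , drop = FALSE]
  if (nrow(a) == 0L) return(NULL)
  key <- !duplicated(paste(a$resno, a$insert, sep = "\r"))
  r <- a[key, c("resno", "insert", "resid"), drop = FALSE]
  r[order(r$resno, r$insert), , drop = FALSE]
}

ionizable_set <- function() c("GLU", "ASP", "SER", "THR", "TYR", "LYS", "ARG", "HIS")

#' Identify the Walker A lysine and its K+1 / K-3 neighbours
#'
#' The Walker A (P-loop) lysine is found geometrically: among all lysines, the
#' one whose NZ atom is nearest to any beta-phosphate oxygen and within the
#' cutoff (5 ångström). NZ is used because it is the chemically interacting
#' atom, contacting O1B and O2G. Ties break by chain ID then residue number.
#' K+1 is the next residue in the same chain (a warning flag is raised when it
#' is not Ser/Thr, as in some kinases where a glycine sits there), K-3 the
#' residue three before the lysine.
#'
#' @param site a `ploop_site` with beta-phosphate oxygens mapped.
#' @param model a `ploop_structure`.
#' @param config a [ploop_config()].
#' @return list with atom tables `lys_wa`, `k_plus_1`, `k_minus_3` (either may
#'   be `NULL` if the chain ends) and `k1_not_st` flag; `NULL` when no lysine
#'   qualifies (site rejected upstream with reason "no P-loop Lys").
#' @export
find_walker_a <- function(site, model, config = ploop_config()) {
  lig <- site$ligand$atoms
  bo <- lig[lig$elety %in% c("O1B", "O2B", "O3B"), , drop = FALSE]
  if (nrow(bo) == 0L) return(NULL)
  a <- model$atoms
  nz <- a[!a$het & a$resid == "LYS" & a$elety == "NZ", , drop = FALSE]
  if (nrow(nz) == 0L) return(NULL)
  bm <- axyz(bo)
  dmin <- apply(axyz(nz), 1, function(p) min(dist_to(p, bm)))
  ok <- dmin <= config$lys_beta
  if (!any(ok)) return(NULL)
  nz <- nz[ok, , drop = FALSE]; dmin <- dmin[ok]
  sel <- order(dmin, nz$chain, nz$resno)[1]
  ch <- nz$chain[sel]; k <- nz$resno[sel]; ins <- nz$insert[sel]

  lys <- res_atoms(model, ch, k, ins)
  resl <- chain_residues(model, ch)
  i <- which(resl$resno == k & resl$insert == ins)
  nxt <- if (length(i) && i < nrow(resl)) resl[i + 1L, ] else NULL
  prv <- if (length(i) && i > 3L) resl[i - 3L, ] else NULL
  k1 <- if (!is.null(nxt)) res_atoms(model, ch, nxt$resno, nxt$insert) else NULL
  k3 <- if (!is.null(prv)) res_atoms(model, ch, prv$resno, prv$insert) else NULL
  list(lys_wa = lys, k_plus_1 = k1, k_minus_3 = k3,
       k1_not_st = !is.null(k1) && !k1$resid[1] %in% c("SER", "THR"))
}

#' Identify the Walker B aspartate/glutamate
#'
#' Candidate carboxylates are all Asp/Glu residues in the chain owning K+1
#' whose minimum carboxylate-oxygen to K+1-hydroxyl-oxygen distance is within
#' the search cutoff (5 ångström; residues further are not considered).
#' Primary rule: the nearest candidate whose three N-terminal neighbours
#' (i-1, i-2, i-3 in author sequence order) are all outside the ionizable set
#' {Glu, Asp, Ser, Thr, Tyr, Lys, Arg, His} — the Walker B motif is four
#' hydrophobics followed by the aspartate. If no candidate passes that window
#' check, the nearest candidate is returned with `fallback = TRUE`. If the
#' candidate set is empty the site is "open" and the result is absent.
#'
#' @param k_plus_1 atom table of the K+1 residue (needs OG or OG1).
#' @param model a `ploop_structure`.
#' @param config a [ploop_config()].
#' @return list with `wb_residue` (atom table or `NULL`), `fallback` flag and
#'   `distance` (min carboxylate-O to hydroxyl-O, ångström, or `NA`).
#' @export
find_walker_b <- function(k_plus_1, model, config = ploop_config()) {
  none <- list(wb_residue = NULL, fallback = FALSE, distance = NA_real_)
  if (is.null(k_plus_1)) return(none)
  hyd <- k_plus_1[k_plus_1$elety %in% c("OG", "OG1"), , drop = FALSE]
  if (nrow(hyd) == 0L) return(none)
  p <- as.numeric(axyz(hyd)[1, ])
  ch <- k_plus_1$chain[1]
  resl <- chain_residues(model, ch)
  if (is.null(resl)) return(none)
  cand <- resl[resl$resid %in% c("ASP", "GLU"), , drop = FALSE]
  # exclude K+1 itself (cannot be its own partner; relevant only for odd inputs)
  cand <- cand[!(cand$resno == k_plus_1$resno[1] &
                   cand$insert == k_plus_1$insert[1]), , drop = FALSE]
  if (nrow(cand) == 0L) return(none)
  dmin <- rep(NA_real_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ra <- res_atoms(model, ch, cand$resno[i], cand$insert[i])
    co <- ra[ra$elety %in% c("OD1", "OD2", "OE1", "OE2"), , drop = FALSE]
    if (nrow(co)) dmin[i] <- min(dist_to(p, axyz(co)))
  }
  keep <- !is.na(dmin) & dmin <= config$wb_search
  cand <- cand[keep, , drop = FALSE]; dmin <- dmin[keep]
  if (nrow(cand) == 0L) return(none)
  ord <- order(dmin, cand$resno, cand$insert)
  cand <- cand[ord, , drop = FALSE]; dmin <- dmin[ord]

  window_ok <- function(resno, insert) {
    i <- which(resl$resno == resno & resl$insert == insert)
    if (!length(i) || i < 4L) return(FALSE)
    all(!resl$resid[(i - 3L):(i - 1L)] %in% ionizable_set())
  }
  for (i in seq_len(nrow(cand))) {
    if (window_ok(cand$resno[i], cand$insert[i])) {
      return(list(
        wb_residue = res_atoms(model, ch, cand$resno[i], cand$insert[i]),
        fallback = FALSE, distance = round(dmin[i], 2)))
    }
  }
  list(wb_residue = res_atoms(model, ch, cand$resno[1], cand$insert[1]),
       fallback = TRUE, distance = round(dmin[1], 2))
}

#' Identify the Switch I threonine/serine
#'
#' In TRAFAC-class NTPases a conserved Ser/Thr outside the Walker A motif
#' coordinates Mg2+ with its side-chain hydroxyl as shell ligand #3. Returns
#' the Ser/Thr (other than K+1) whose side-chain oxygen occupies a shell
#' position; absent when that position is taken by a water.
#'
#' @param site a `ploop_site`.
#' @param annotation a `ploop_annotation` (to exclude K+1).
#' @param shell a `ploop_shell` from [mg_coordination_shell()].
#' @param model a `ploop_structure`.
#' @return atom table of the Switch I residue, or `NULL`.
#' @export
find_switch_i <- function(site, annotation, shell, model) {
  lg <- shell$ligands
  k1 <- annotation$k_plus_1
  for (i in seq_len(nrow(lg))) {
    if (!lg$het[i] && lg$resid[i] %in% c("SER", "THR") &&
        lg$elety[i] %in% c("OG", "OG1")) {
      if (!is.null(k1) && lg$chain[i] == k1$chain[1] &&
          lg$resno[i] == k1$resno[1] && lg$insert[i] == k1$insert[1]) next
      return(res_atoms(model, lg$chain[i], lg$resno[i], lg$insert[i]))
    }
  }
  NULL
}

#' Identify the apical catalytic water
#'
#' The catalytic water sits near the gamma-phosphorus (or the central atom of
#' its mimic) almost in line with the O3B bridge: among waters whose oxygen is
#' 2-4 ångström from the centre X, the one maximising the O3B-X-Ow angle is
#' returned, provided that angle is at least 140 degrees. For vanadate the
#' apical oxygen of the VO4 moiety itself occupies the catalytic-water
#' position and is returned as its surrogate. Absence is a valid result.
#'
#' @param site a `ploop_site` with a gamma-phosphate or mimic.
#' @param model a `ploop_structure`.
#' @param config a [ploop_config()].
#' @return single-residue atom table (a water, or the vanadate apical oxygen
#'   row), or `NULL`.
#' @export
find_wcat <- function(site, model, config = ploop_config()) {
  ctr <- gamma_center_atom(site)
  if (is.null(ctr)) return(NULL)
  x <- as.numeric(axyz(ctr)[1, ])
  lig <- site$ligand$atoms
  o3b <- lig[lig$elety == "O3B", , drop = FALSE]
  if (nrow(o3b) == 0L) return(NULL)
  b <- as.numeric(axyz(o3b)[1, ])

  if (!is.null(site$ligand$mimic) && toupper(site$ligand$mimic$code) == "VO4") {
    per <- site$ligand$mimic$atoms
    per <- per[per$elesy == "O", , drop = FALSE]
    ang <- apply(axyz(per), 1, function(p) angle_deg(b, x, p))
    i <- which.max(ang)
    if (ang[i] >= config$wcat_angle) return(per[i, , drop = FALSE])
    return(NULL)
  }
  a <- model$atoms
  wat <- a[a$resid == "HOH" & a$elesy == "O", , drop = FALSE]
  if (nrow(wat) == 0L) return(NULL)
  d <- dist_to(x, axyz(wat))
  ok <- d >= config$wcat_dist[1] & d <= config$wcat_dist[2]
  if (!any(ok)) return(NULL)
  wat <- wat[ok, , drop = FALSE]
  ang <- apply(axyz(wat), 1, function(p) angle_deg(b, x, p))
  i <- which.max(ang)
  if (ang[i] < config$wcat_angle) return(NULL)
  wat[i, , drop = FALSE]
}

#' Polar atoms coordinating the catalytic water
#'
#' All protein/solvent N and O atoms (excluding the gamma-moiety itself and
#' W_cat's own oxygen) within the polar-contact radius (3.6 ångström) of the
#' catalytic water, sorted by distance. The nearest Asp/Glu carboxylate oxygen
#' among them defines the W_cat-coordinating "catalytic" carboxylate.
#'
#' @param wcat single-row atom table (the W_cat oxygen).
#' @param site a `ploop_site` (its gamma moiety is excluded).
#' @param model a `ploop_structure`.
#' @param config a [ploop_config()].
#' @return list with `contacts` (data frame `residue`, `resid`, `atom`,
#'   `distance`) and `catalytic_carboxylate` (atom table or `NULL`).
#' @export
wcat_polar_contacts <- function(wcat, site, model, config = ploop_config()) {
  p <- as.numeric(axyz(wcat)[1, ])
  a <- model$atoms
  pool <- a[a$elesy %in% c("N", "O"), , drop = FALSE]
  # exclude the gamma moiety (and the nucleotide) and W_cat itself
  excl <- rbind(site$ligand$atoms,
                if (!is.null(site$ligand$mimic)) site$ligand$mimic$atoms)
  keyp <- paste(pool$chain, pool$resno, pool$insert, pool$elety, sep = "\r")
  keye <- paste(excl$chain, excl$resno, excl$insert, excl$elety, sep = "\r")
  keyw <- paste(wcat$chain, wcat$resno, wcat$insert, wcat$elety, sep = "\r")
  pool <- pool[!(keyp %in% c(keye, keyw)), , drop = FALSE]
  if (nrow(pool) == 0L) {
    return(list(contacts = data.frame(), catalytic_carboxylate = NULL))
  }
  d <- dist_to(p, axyz(pool))
  ok <- d <= config$polar_contact
  pool <- pool[ok, , drop = FALSE]; d <- d[ok]
  ord <- order(d, pool$chain, pool$resno, pool$elety)
  pool <- pool[ord, , drop = FALSE]; d <- d[ord]
  contacts <- data.frame(
    residue = sprintf("%s/%s%d%s", pool$chain, pool$resid, pool$resno, pool$insert),
    resid = pool$resid, atom = pool$elety, distance = round(d, 2),
    stringsAsFactors = FALSE)
  cc <- NULL
  icc <- which(pool$resid %in% c("ASP", "GLU") &
                 pool$elety %in% c("OD1", "OD2", "OE1", "OE2"))
  if (length(icc)) {
    j <- icc[1]
    cc <- res_atoms(model, pool$chain[j], pool$resno[j], pool$insert[j])
  }
  list(contacts = contacts, catalytic_carboxylate = cc)
}

#' Annotate a catalytic site
#'
#' Runs the full geometric annotation: Walker A lysine with its K+1 and K-3
#' neighbours, Walker B carboxylate (with fallback flag), cofactor shell,
#' Switch I Ser/Thr, catalytic water and its polar contacts.
#'
#' @param site a `ploop_site`.
#' @param model a `ploop_structure`.
#' @param config a [ploop_config()].
#' @return object of class `ploop_annotation`: list with `lys_wa`, `k_plus_1`,
#'   `k_minus_3`, `k1_not_st`, `wb_residue`, `wb_fallback`, `wb_distance`,
#'   `shell` (or `NULL` when no ion), `switch_i`, `wcat`, `wcat_contacts`,
#'   `catalytic_carboxylate`, `rejected` (reason string or `NA`).
#' @export
annotate_site <- function(site, model, config = ploop_config()) {
  ann <- list(lys_wa = NULL, k_plus_1 = NULL, k_minus_3 = NULL,
              k1_not_st = FALSE, wb_residue = NULL, wb_fallback = FALSE,
              wb_distance = NA_real_, shell = NULL, switch_i = NULL,
              wcat = NULL, wcat_contacts = NULL, catalytic_carboxylate = NULL,
              rejected = NA_character_)
  class(ann) <- "ploop_annotation"
  wa <- find_walker_a(site, model, config)
  if (is.null(wa)) {
    ann$rejected <- "no P-loop Lys"
    return(ann)
  }
  ann[c("lys_wa", "k_plus_1", "k_minus_3", "k1_not_st")] <-
    wa[c("lys_wa", "k_plus_1", "k_minus_3", "k1_not_st")]
  wb <- find_walker_b(ann$k_plus_1, model, config)
  ann$wb_residue <- wb$wb_residue
  ann$wb_fallback <- wb$fallback
  ann$wb_distance <- wb$distance
  if (!is.null(site$ion)) {
    ann$shell <- mg_coordination_shell(site, model, ann, config)
    ann$switch_i <- find_switch_i(site, ann, ann$shell, model)
  }
  ann$wcat <- find_wcat(site, model, config)
  if (!is.null(ann$wcat)) {
    pc <- wcat_polar_contacts(ann$wcat, site, model, config)
    ann$wcat_contacts <- pc$contacts
    ann$catalytic_carboxylate <- pc$catalytic_carboxylate
  }
  ann
}

#' @export
print.ploop_annotation <- function(x, ...) {
  lab <- function(r) if (is.null(r)) "absent" else res_label(r)
  cat("<ploop_annotation>\n")
  if (!is.na(x$rejected)) {
    cat("  rejected:", x$rejected, "\n")
    return(invisible(x))
  }
  cat("  Lys[WA]    :", lab(x$lys_wa), "\n")
  cat("  K+1        :", lab(x$k_plus_1),
      if (x$k1_not_st) "(not Ser/Thr)" else "", "\n")
  cat("  K-3        :", lab(x$k_minus_3), "\n")
  cat(sprintf("  Walker B   : %s%s (d = %s A)\n", lab(x$wb_residue),
              if (x$wb_fallback) " [fallback]" else "",
              ifelse(is.na(x$wb_distance), "NA", format(x$wb_distance))))
  cat("  Switch I   :", lab(x$switch_i), "\n")
  cat("  W_cat      :", lab(x$wcat), "\n")
  cat("  cat. COO-  :", lab(x$catalytic_carboxylate), "\n")
  invisible(x)
}
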