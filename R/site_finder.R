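# one hetero residue as a list of its atom rows
het_residues <- function(model, codes) {
  a <- model$atoms
  sel <- a[a$resid %in% codes, , drop = FALSE]
  if (nrow(sel) == 0L) return(list())
  key <- paste(sel$chain, sel$resno, sel$insert, sel$resid, sep = "\r")
  lapply(split(seq_len(nrow(sel)), key), function(i) sel[i, , drop = FALSE])
}

#' Locate candidate Mg-NTP catalytic sites
#'
#' One candidate per nucleotide hetero-residue whose component code is in the
#' configured lists (native NTP, non-hydrolyzable NTP analogue, or NDP). For
#' NDP ligands the nearest gamma-phosphate-mimic residue whose central atom
#' (Al/Be/Mg/V/P) lies within the association cutoff (3.5 ångström) of the
#' terminal O3B oxygen is attached, forming a composite ligand. Each candidate
#' is then completed by [find_cofactor_ion()] and classified by
#' [classify_ligand()]. Nucleotides missing the beta-phosphorus are rejected
#' with reason `"incomplete ligand"`.
#'
#' @param model a `ploop_structure`.
#' @param config a [ploop_config()].
#' @return list of `ploop_site` objects (pre-QC). Rejected candidates are
#'   returned too, with `reject_reason` set.
#' @export
find_nucleotide_sites <- function(model, config = ploop_config()) {
  comp <- config$components
  nuc_codes <- c(comp$ntp, comp$ntp_analog, comp$ndp)
  nucs <- het_residues(model, nuc_codes)
  mimics <- het_residues(model, comp$mimic)
  sites <- list()
  for (nuc in nucs) {
    code <- nuc$resid[1]
    site <- structure(list(
      ligand = list(code = code, chain = nuc$chain[1], resno = nuc$resno[1],
                    atoms = nuc, mimic = NULL),
      ion = NULL, ligand_class = NA_character_, qc = NULL,
      reject_reason = NA_character_), class = "ploop_site")
    if (!"PB" %in% nuc$elety) {
      site$reject_reason <- "incomplete ligand"
      sites[[length(sites) + 1L]] <- site
      next
    }
    if (code %in% comp$ndp && length(mimics)) {
      o3b <- nuc[nuc$elety == "O3B", , drop = FALSE]
      if (nrow(o3b)) {
        p <- as.numeric(axyz(o3b)[1, ])
        best <- NULL; bestd <- Inf
        for (mm in mimics) {
          ctr_el <- mimic_center_element(mm$resid[1])
          ctr <- mm[mm$elesy == ctr_el, , drop = FALSE]
          if (nrow(ctr) == 0L) next
          d <- dist_pt(p, as.numeric(axyz(ctr)[1, ]))
          if (d <= config$mimic_assoc && d < bestd) {
            bestd <- d
            best <- list(code = mm$resid[1], atoms = mm,
                         center = ctr[1, , drop = FALSE], o3b_dist = d)
          }
        }
        site$ligand$mimic <- best
      }
    }
    site$ion <- find_cofactor_ion(model, site, config)
    site$ligand_class <- classify_ligand(site)
    sites[[length(sites) + 1L]] <- site
  }
  unname(sites)
}

#' Classify the bound species of a catalytic site
#'
#' The four classes partition accepted sites: `native` (ATP/GTP),
#' `non_hydrolyzable` (imido/methylene/thio triphosphate analogues),
#' `substrate_analog` (NDP with BeF3 or AlF3, ground-state mimics) and
#' `ts_analog` (NDP with AlF4, MgF3 or VO4, transition-state mimics). For
#' metal fluorides the species is confirmed geometrically by
#' [validate_fluoride_geometry()], which overrides the deposited component
#' code on conflict — misassigned fluoride moieties occur in the PDB. An NDP
#' without any gamma moiety is `ndp_only` (excluded from accepted sites; when
#' a detached phosphate is attached the site is the post-hydrolysis state, see
#' [beta_pi_distance()]).
#'
#' @param site a `ploop_site`.
#' @param config a [ploop_config()].
#' @return one of `"native"`, `"non_hydrolyzable"`, `"substrate_analog"`,
#'   `"ts_analog"`, `"ndp_only"`.
#' @export
classify_ligand <- function(site, config = ploop_config()) {
  comp <- config$components
  code <- site$ligand$code
  if (code %in% comp$ntp) return("native")
  if (code %in% comp$ntp_analog) return("non_hydrolyzable")
  if (code %in% comp$ndp) {
    mm <- site$ligand$mimic
    if (is.null(mm) || toupper(mm$code) %in% c("PO4", "PI")) return("ndp_only")
    sp <- validate_fluoride_geometry(mm$atoms)
    if (sp == "unknown") {
      # fall back on the deposited code when geometry is inconclusive
      sp <- switch(toupper(mm$code), ALF = "AlF4", AF3 = "AlF3", MGF = "MgF3",
                   BEF = "BeF3", VO4 = "VO4", "unknown")
    }
    if (sp %in% c("AlF4", "MgF3", "VO4")) return("ts_analog")
    if (sp %in% c("BeF3", "AlF3")) return("substrate_analog")
    return("ndp_only")
  }
  "ndp_only"
}

#' Determine a fluoride/vanadate species from its geometry
#'
#' Metal-fluoride gamma-phosphate mimics are distinguished by central-atom
#' element, peripheral-atom count and planarity: four fluorines approximately
#' square-planar (every F within 0.3 ångström of the common least-squares
#' plane, which also holds the central atom) is AlF4; three fluorines
#' trigonal-planar with the centre are AlF3/MgF3/BeF3 according to the central
#' element; vanadium with four oxygens is VO4. The distinction matters:
#' four-fluorine square-planar species are transition-state analogues while
#' the three-fluorine species mimic the ground state, and deposited component
#' codes are sometimes wrong.
#'
#' @param mimic_atoms atom table of the mimic residue.
#' @param planarity_tol max out-of-plane deviation, ångström (default 0.3).
#' @return `"AlF4"`, `"AlF3"`, `"MgF3"`, `"BeF3"`, `"VO4"` or `"unknown"`.
#' @export
validate_fluoride_geometry <- function(mimic_atoms, planarity_tol = 0.3) {
  el <- mimic_atoms$elesy
  ctr_el <- intersect(c("AL", "MG", "BE", "V", "P"), el)
  if (length(ctr_el) == 0L) return("unknown")
  ctr_el <- ctr_el[1]
  ctr <- as.numeric(axyz(mimic_atoms[el == ctr_el, , drop = FALSE])[1, ])
  per <- mimic_atoms[el %in% c("F", "O") & el != ctr_el, , drop = FALSE]
  if (ctr_el == "V") {
    return(if (sum(per$elesy == "O") == 4L) "VO4" else "unknown")
  }
  fl <- per[per$elesy == "F", , drop = FALSE]
  nf <- nrow(fl)
  if (nf < 3L) return("unknown")
  if (nf >= 4L) {
    pts <- rbind(axyz(fl), matrix(ctr, 1))
    dev <- plane_deviation(pts)
    if (dev <= planarity_tol) return("AlF4")
    return("unknown")
  }
  # three fluorines: trigonal-planar with the centre in-plane
  pts <- rbind(axyz(fl), matrix(ctr, 1))
  if (plane_deviation(pts) <= planarity_tol) {
    return(switch(ctr_el, AL = "AlF3", MG = "MgF3", BE = "BeF3", "unknown"))
  }
  "unknown"
}

# max distance of points from their least-squares plane
plane_deviation <- function(pts) {
  c0 <- colMeans(pts)
  s <- svd(sweep(pts, 2, c0))
  normal <- s$v[, 3]
  max(abs(sweep(pts, 2, c0) %*% normal))
}

#' Find the cofactor ion of a candidate site
#'
#' Returns the Mg/Mn/Ca hetero-atom nearest to the midpoint of the O2B and
#' O1G atoms (for mimic-bearing sites the mimic atom standing in O1G's role,
#' i.e. the mimic peripheral atom nearest that midpoint), provided it lies
#' within the association cutoff (3.0 ångström) of either anchor; absence is a
#' valid result recorded by QC.
#'
#' @param model a `ploop_structure`.
#' @param site a `ploop_site`.
#' @param config a [ploop_config()].
#' @return single-row atom data frame, or `NULL`.
#' @export
find_cofactor_ion <- function(model, site, config = ploop_config()) {
  lig <- site$ligand$atoms
  o2b <- lig[lig$elety == "O2B", , drop = FALSE]
  if (nrow(o2b) == 0L) return(NULL)
  p1 <- as.numeric(axyz(o2b)[1, ])
  o1g <- lig[lig$elety == "O1G", , drop = FALSE]
  if (nrow(o1g)) {
    p2 <- as.numeric(axyz(o1g)[1, ])
  } else if (!is.null(site$ligand$mimic)) {
    per <- site$ligand$mimic$atoms
    per <- per[per$elesy %in% c("F", "O"), , drop = FALSE]
    if (nrow(per) == 0L) return(NULL)
    d <- dist_to(p1, axyz(per))
    p2 <- as.numeric(axyz(per)[which.min(d), ])
  } else {
    p2 <- p1
  }
  mid <- (p1 + p2) / 2
  a <- model$atoms
  ions <- a[a$het & a$resid %in% config$components$ion &
              a$elesy %in% config$components$ion, , drop = FALSE]
  if (nrow(ions) == 0L) return(NULL)
  im <- axyz(ions)
  dmid <- dist_to(mid, im)
  ord <- order(dmid, ions$chain, ions$resno)
  for (i in ord) {
    p <- as.numeric(im[i, ])
    if (dist_pt(p, p1) <= config$ion_assoc || dist_pt(p, p2) <= config$ion_assoc) {
      return(ions[i, , drop = FALSE])
    }
  }
  NULL
}

#' Quality-control a catalytic site
#'
#' The acceptance flags of the survey: a Walker A lysine NZ within 5 ångström
#' of a beta-phosphate oxygen; a gamma-phosphate or mimic present;
#' \[Ser/Thr\]K+1 hydroxyl to Mg2+ at or under 2.5 ångström (correct Mg
#' binding and adequate local resolution); Mg2+ to the nearest Walker B
#' carboxylate oxygen at or under 6 ångström (neither direct coordination of
#' the ion by the acid nor a disassembled site). `all_pass` is the conjunction
#' of the four flags (an absent ion fails the two Mg-based flags).
#'
#' @param site a `ploop_site`.
#' @param annotation a `ploop_annotation` for this site.
#' @param config a [ploop_config()].
#' @return list of logicals `lys_near_beta`, `gamma_moiety_present`,
#'   `k1_mg_ok`, `mg_wb_ok`, `all_pass`, plus the measured `k1_mg_distance`
#'   and `mg_wb_distance`.
#' @export
qc_site <- function(site, annotation, config = ploop_config()) {
  lig <- site$ligand$atoms
  qc <- list(lys_near_beta = FALSE, gamma_moiety_present = FALSE,
             k1_mg_ok = FALSE, mg_wb_ok = FALSE,
             k1_mg_distance = NA_real_, mg_wb_distance = NA_real_)

  qc$lys_near_beta <- !is.null(annotation$lys_wa)
  # a detached/attached inorganic phosphate marks a post-hydrolysis site,
  # not a gamma-phosphate mimic
  qc$gamma_moiety_present <- "PG" %in% lig$elety ||
    (!is.null(site$ligand$mimic) &&
       !toupper(site$ligand$mimic$code) %in% c("PO4", "PI"))
  if (!is.null(site$ion)) {
    p0 <- as.numeric(axyz(site$ion)[1, ])
    k1 <- annotation$k_plus_1
    if (!is.null(k1)) {
      hyd <- k1[k1$elety %in% c("OG", "OG1"), , drop = FALSE]
      if (nrow(hyd)) {
        qc$k1_mg_distance <- round(dist_pt(p0, as.numeric(axyz(hyd)[1, ])), 2)
        qc$k1_mg_ok <- qc$k1_mg_distance <= config$k1_mg
      }
    }
    wb <- annotation$wb_residue
    if (!is.null(wb)) {
      co <- wb[wb$elety %in% c("OD1", "OD2", "OE1", "OE2"), , drop = FALSE]
      if (nrow(co)) {
        qc$mg_wb_distance <- round(min(dist_to(p0, axyz(co))), 2)
        qc$mg_wb_ok <- qc$mg_wb_distance <= config$mg_wb
      }
    }
  }
  qc$all_pass <- qc$lys_near_beta && qc$gamma_moiety_present &&
    qc$k1_mg_ok && qc$mg_wb_ok
  qc
}

#' @export
print.ploop_site <- function(x, ...) {
  mim <- if (!is.null(x$ligand$mimic)) paste0(":", x$ligand$mimic$code) else ""
  cat(sprintf("<ploop_site> %s%s (chain %s, %d) class=%s ion=%s%s\n",
              x$ligand$code, mim, x$ligand$chain, x$ligand$resno,
              x$ligand_class %||% "?",
              if (is.null(x$ion)) "absent" else x$ion$resid[1],
              if (!is.na(x$reject_reason %||% NA)) paste0(" [rejected: ",
                                                          x$reject_reason, "]") else ""))
  invisible(x)
}
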