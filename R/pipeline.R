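#' Survey a set of structure files for catalytic sites
#'
#' The full pipeline over one or more PDB/mmCIF files: candidate detection,
#' ligand assembly and classification, motif annotation, QC, all diagnostic
#' measurements and (optionally) the Walker B aspartate's relative solvent
#' accessibility. Every candidate is either an accepted row or a rejected row
#' with a machine-readable reason, so accepted + rejected = candidates.
#'
#' @param paths character vector of structure files, or a directory (all
#'   `.pdb`/`.cif` files in it).
#' @param config a [ploop_config()].
#' @param compute_sasa compute `asp_wb_rel_sasa` per site (the slowest step).
#' @param sasa_n_points quadrature size passed to [relative_sasa()].
#' @return list with `records` (data frame, one row per classifiable site,
#'   with QC flags; headline aggregates should filter on `qc_pass`) and
#'   `rejects` (candidates dropped outright, with machine-readable `reason`:
#'   `"incomplete ligand"`, `"no P-loop Lys"` or `"ndp_only"`).
#' @export
scan_structures <- function(paths, config = ploop_config(),
                            compute_sasa = FALSE, sasa_n_points = 480) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(pdb|ent|cif|mmcif)$",
                        full.names = TRUE)
  }
  if (!length(paths)) stop("no structure files found")
  records <- NULL
  rejects <- NULL
  for (p in sort(paths)) {
    model <- read_structure(p)
    sites <- find_nucleotide_sites(model, config)
    for (si in seq_along(sites)) {
      site <- sites[[si]]
      tag <- sprintf("%s:%d", site$ligand$chain, site$ligand$resno)
      if (!is.na(site$reject_reason)) {
        rejects <- rbind(rejects, data.frame(structure_id = model$id,
                                             site = tag,
                                             reason = site$reject_reason,
                                             stringsAsFactors = FALSE))
        next
      }
      ann <- annotate_site(site, model, config)
      if (!is.na(ann$rejected)) {
        rejects <- rbind(rejects, data.frame(structure_id = model$id,
                                             site = tag, reason = ann$rejected,
                                             stringsAsFactors = FALSE))
        next
      }
      if (identical(site$ligand_class, "ndp_only")) {
        # bare NDP or post-hydrolysis NDP+Pi: not an accepted catalytic site
        rejects <- rbind(rejects, data.frame(structure_id = model$id,
                                             site = tag, reason = "ndp_only",
                                             stringsAsFactors = FALSE))
        next
      }
      records <- rbind(records,
                       site_record(site, ann, model, config, compute_sasa,
                                   sasa_n_points, tag))
    }
  }
  if (is.null(records)) records <- write_site_records_template()
  if (is.null(rejects)) {
    rejects <- data.frame(structure_id = character(0), site = character(0),
                          reason = character(0), stringsAsFactors = FALSE)
  }
  list(records = records, rejects = rejects)
}

write_site_records_template <- function() {
  cols <- site_record_columns()
  as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
}

site_record <- function(site, ann, model, config, compute_sasa, sasa_n_points,
                        tag) {
  qc <- qc_site(site, ann, config)
  d <- wb_k1_distance(ann)
  shell <- ann$shell
  rel <- NA_real_
  if (compute_sasa && !is.null(ann$wb_residue)) {
    wb <- ann$wb_residue
    rel <- tryCatch(
      relative_sasa(model, wb$chain[1], wb$resno[1], wb$insert[1],
                    n_points = sasa_n_points)$relative,
      error = function(e) NA_real_)
  }
  lab <- function(r) if (is.null(r)) NA_character_ else res_label(r)
  bpi <- beta_pi_distance(site, model, config)
  warn <- c(if (ann$k1_not_st) "k1_not_ser_thr",
            if (ann$wb_fallback) "wb_fallback",
            if (!is.null(shell) && !shell$complete) "shell_incomplete",
            if (isTRUE(bpi$bonding)) "pi_present")
  data.frame(
    structure_id = model$id, chain = site$ligand$chain, site = tag,
    ligand_class = site$ligand_class,
    resolution = model$resolution %||% NA_real_,
    lys_wa = lab(ann$lys_wa), k_plus_1 = lab(ann$k_plus_1),
    k_minus_3 = lab(ann$k_minus_3), wb_residue = lab(ann$wb_residue),
    wb_fallback = ann$wb_fallback,
    wb_k1_distance = d,
    hnk3_o2g_distance = hnk3_gamma_distance(ann, site),
    k1_mg_distance = qc$k1_mg_distance,
    mg_wb_distance = qc$mg_wb_distance,
    shell_n = if (is.null(shell)) 0L else nrow(shell$ligands),
    shell_edge_mean = if (is.null(shell) || !length(shell$edges)) NA_real_
                      else round(mean(shell$edges), 3),
    hbond_class = if (is.na(d)) NA_character_ else classify_hbond(d),
    delta_pka = if (is.na(d)) NA_real_ else round(delta_pka_estimate(d), 2),
    asp_wb_rel_sasa = if (is.na(rel)) NA_real_ else round(rel, 2),
    qc_pass = qc$all_pass,
    warnings = if (length(warn)) paste(warn, collapse = ";") else "",
    stringsAsFactors = FALSE)
}

#' Annotate one structure and return a JSON-ready report
#'
#' Human-readable single-structure report: one entry per catalytic site with
#' the full motif annotation, shell and measurements. Residues are identified
#' as `chain/RESNAMEnumber` in author numbering.
#'
#' @param path structure file.
#' @param config a [ploop_config()].
#' @param json write JSON to this path (optional).
#' @return the report list, invisibly when `json` given.
#' @export
annotate_structure <- function(path, config = ploop_config(), json = NULL) {
  model <- read_structure(path)
  sites <- find_nucleotide_sites(model, config)
  lab <- function(r) if (is.null(r)) NULL else res_label(r)
  entries <- list()
  for (site in sites) {
    if (!is.na(site$reject_reason)) {
      entries[[length(entries) + 1L]] <- list(
        ligand = site$ligand$code, chain = site$ligand$chain,
        resno = site$ligand$resno, rejected = site$reject_reason)
      next
    }
    ann <- annotate_site(site, model, config)
    qc <- qc_site(site, ann, config)
    shell <- ann$shell
    entries[[length(entries) + 1L]] <- list(
      ligand = site$ligand$code,
      mimic = if (!is.null(site$ligand$mimic)) site$ligand$mimic$code else NULL,
      chain = site$ligand$chain, resno = site$ligand$resno,
      ligand_class = site$ligand_class,
      ion = if (is.null(site$ion)) "absent" else
        sprintf("%s/%s%d", site$ion$chain[1], site$ion$resid[1],
                site$ion$resno[1]),
      rejected = if (is.na(ann$rejected)) NULL else ann$rejected,
      lys_wa = lab(ann$lys_wa), k_plus_1 = lab(ann$k_plus_1),
      k_minus_3 = lab(ann$k_minus_3), wb_residue = lab(ann$wb_residue),
      wb_fallback = ann$wb_fallback, wb_distance = ann$wb_distance,
      switch_i = lab(ann$switch_i), wcat = lab(ann$wcat),
      catalytic_carboxylate = lab(ann$catalytic_carboxylate),
      shell = if (is.null(shell)) NULL else list(
        n = nrow(shell$ligands), complete = shell$complete,
        positions = shell$ligands$pos,
        atoms = sprintf("%s/%s%d:%s", shell$ligands$chain,
                        shell$ligands$resid, shell$ligands$resno,
                        shell$ligands$elety),
        edge_mean = if (length(shell$edges)) round(mean(shell$edges), 3) else NULL),
      qc = qc[c("lys_near_beta", "gamma_moiety_present", "k1_mg_ok",
                "mg_wb_ok", "all_pass")],
      wb_k1_distance = wb_k1_distance(ann),
      hnk3_o2g_distance = hnk3_gamma_distance(ann, site))
  }
  report <- list(structure = model$id, resolution = model$resolution,
                 n_sites = length(entries), sites = entries)
  if (!is.null(json)) {
    jsonlite::write_json(report, json, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    return(invisible(report))
  }
  report
}

#' Fetch PDB entries for a user-supplied accession list
#'
#' Convenience helper for populating a reference directory; it simply
#' downloads `https://files.rcsb.org/download/<ID>.pdb` for each accession.
#' It requires network access and is not used by any other function.
#'
#' @param ids character vector of 4-character PDB accessions.
#' @param dir destination directory.
#' @return paths of the files written (errors are reported per id).
#' @export
fetch_pdb <- function(ids, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(ids, function(id) {
    dest <- file.path(dir, paste0(toupper(id), ".pdb"))
    url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
    tryCatch({
      utils::download.file(url, dest, quiet = TRUE, mode = "wb")
      dest
    }, error = function(e) {
      warning("could not fetch ", id, ": ", conditionMessage(e))
      NA_character_
    })
  }, character(1))
}
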