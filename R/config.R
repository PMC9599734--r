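#' Pipeline configuration
#'
#' All geometric cutoffs of the site-detection and annotation pipeline, plus
#' the chemical-component code lists. Defaults are the values used throughout
#' the survey; every one of them can be overridden, either by arguments here or
#' by a YAML file (see [read_config()]). Component-code lists are kept in a
#' shipped, user-editable YAML (`inst/extdata/components.yaml`) because PDB
#' chemical dictionaries evolve.
#'
#' Cutoffs (all in ångström unless noted):
#' \describe{
#'   \item{lys_beta}{max Lys NZ to beta-phosphate O distance for the Walker A
#'     lysine (default 5).}
#'   \item{k1_mg}{max \[Ser/Thr\]K+1 hydroxyl O to Mg2+ distance passing QC
#'     (default 2.5).}
#'   \item{mg_wb}{max Mg2+ to Walker B carboxylate O distance passing QC
#'     (default 6).}
#'   \item{wb_search}{max carboxylate-O to K+1 hydroxyl-O distance for Walker B
#'     candidates (default 5).}
#'   \item{shell}{Mg2+ first-shell membership cutoff, Mg to O/N (default 2.6).}
#'   \item{mimic_assoc}{max mimic central atom (Al/Be/Mg/V/P) to O3B distance
#'     to treat an NDP + mimic pair as one composite ligand (default 3.5).}
#'   \item{ion_assoc}{max ion distance from the O2B/O1G anchors (default 3.0).}
#'   \item{wcat_angle}{min O3B--X--Ow angle in degrees for the apical catalytic
#'     water (default 140).}
#'   \item{wcat_dist}{allowed Ow to gamma-center distance range (default
#'     c(2, 4)).}
#'   \item{polar_contact}{polar-contact radius around W_cat and the
#'     gamma-moiety (default 3.6).}
#'   \item{hbond_moderate}{upper bound of a "moderate" contact; beyond it and
#'     up to `polar_contact` a contact is "weak" (default 3.2).}
#'   \item{resolution_max}{resolution filter used for headline aggregates
#'     (default 2.5).}
#' }
#'
#' @param ... named overrides for any of the fields described above.
#' @return A named list of class `ploop_config`.
#' @export
#' @examples
#' cfg <- ploop_config(resolution_max = 3.0)
#' cfg$lys_beta
ploop_config <- function(...) {
  cfg <- list(
    lys_beta       = 5.0,
    k1_mg          = 2.5,
    mg_wb          = 6.0,
    wb_search      = 5.0,
    shell          = 2.6,
    mimic_assoc    = 3.5,
    ion_assoc      = 3.0,
    wcat_angle     = 140,
    wcat_dist      = c(2.0, 4.0),
    polar_contact  = 3.6,
    hbond_moderate = 3.2,
    resolution_max = 2.5,
    components     = default_components()
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(all(vapply(
    cfg[c("lys_beta", "k1_mg", "mg_wb", "wb_search", "shell", "mimic_assoc",
          "ion_assoc", "wcat_angle", "polar_contact", "hbond_moderate",
          "resolution_max")],
    function(x) is.numeric(x) && all(x > 0), logical(1))))
  class(cfg) <- "ploop_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may override any cutoff and/or the `components` lists; fields not
#' present keep their defaults.
#'
#' @param path YAML file.
#' @return A `ploop_config` list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- ploop_config()
  for (nm in intersect(names(y), names(cfg))) {
    if (nm == "components") {
      cfg$components[names(y$components)] <- y$components
    } else {
      cfg[[nm]] <- y[[nm]]
    }
  }
  cfg
}

# Accepted chemical-component codes per role. NTP: native substrates; NTP
# analogues: beta,gamma-imido (ANP/GNP), beta,gamma-methylene (ACP/GCP) and
# gamma-thio (AGS/GSP) triphosphates; NDP: diphosphates that may carry a
# gamma-phosphate mimic; mimics: metal fluorides, vanadate and inorganic
# phosphate; ions: the divalent cofactors.
default_components <- function() {
  list(
    ntp    = c("ATP", "GTP"),
    ntp_analog = c("ANP", "GNP", "ACP", "GCP", "AGS", "GSP"),
    ndp    = c("ADP", "GDP"),
    mimic  = c("ALF", "AF3", "MGF", "BEF", "VO4", "PO4", "PI"),
    ion    = c("MG", "MN", "CA"),
    water  = c("HOH", "WAT", "DOD")
  )
}

# central atom element per mimic component code
mimic_center_element <- function(code) {
  switch(toupper(code),
    ALF = "AL", AF3 = "AL", MGF = "MG", BEF = "BE",
    VO4 = "V", PO4 = "P", PI = "P",
    NA_character_)
}
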