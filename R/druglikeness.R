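# Header-alias maps: property tables arrive with a variety of column
# spellings (ChEMBL/pkCSM-style exports); headers are matched after
# lowercasing and stripping non-alphanumerics.
.MOLPROP_ALIASES <- list(
  name = c("name", "phenolic", "compound", "molecule"),
  mol_weight = c("molweight", "molecularweight", "mw", "molwt"),
  alogp = c("alogp", "logp"),
  rotatable_bonds = c("rotatablebonds", "nrotatablebonds",
                      "numrotatablebonds", "rotb"),
  psa = c("psa", "polarsurfacearea", "tpsa"),
  hba = c("hba", "hbalipinski", "hbondacceptors", "hbacceptors"),
  hbd = c("hbd", "hbdlipinski", "hbonddonors", "hbdonors"),
  ro5_violations = c("ro5violations", "ro5violationslipinski",
                     "nro5violations", "lipinskiviolations"),
  aromatic_rings = c("aromaticrings", "naromaticrings")
)

.ADMET_ALIASES <- list(
  name = c("name", "phenolic", "compound", "molecule"),
  water_solubility = c("watersolubility", "watersolubilitylogmoll", "logs"),
  caco2 = c("caco2", "caco2permeability", "caco2permeability106cms"),
  intestinal_absorption = c("intestinalabsorption",
                            "intestinalabsorptionhuman",
                            "intestinalabsorptionhumanabsorbed"),
  skin_logkp = c("skinlogkp", "skinpermeability", "logkp"),
  bbb_logbb = c("bbblogbb", "bbbpermeability", "logbb"),
  cns_logps = c("cnslogps", "cnspermeability", "logps"),
  max_tolerated_dose = c("maxtolerateddose", "maxdose", "maxdosehuman",
                         "maxdosehumanlogmgday"),
  hepatotoxic = c("hepatotoxic", "hepatotoxicity"),
  skin_sensitizer = c("skinsensitizer", "skinsensation",
                      "skinsensitisation", "skinsensitization"),
  tpyriformis = c("tpyriformis", "tpyriformistoxicity",
                  "tpyriformistoxicitylogugl"),
  minnow_loglc50 = c("minnowloglc50", "minnowtoxicity", "loglc50",
                     "minnowtoxicitylogmm")
)

.normalizeHeaders <- function(headers, aliases, what) {
  key <- gsub("[^a-z0-9]", "", tolower(headers))
  lookup <- stats::setNames(
    rep(names(aliases), lengths(aliases)), unlist(aliases))
  mapped <- lookup[key]
  if (anyNA(mapped))
    stop("unrecognized ", what, " column(s): ",
         paste(headers[is.na(mapped)], collapse = ", "))
  if (anyDuplicated(mapped))
    stop("duplicate ", what, " column(s) after alias mapping: ",
         paste(unique(mapped[duplicated(mapped)]), collapse = ", "))
  unname(mapped)
}

#' Read a molecular-property table
#'
#' CSV with one compound per row and columns for molecular weight, ALogP,
#' rotatable bonds, polar surface area, Lipinski hydrogen-bond acceptor
#' and donor counts, and aromatic rings. Common header variants are
#' accepted via an alias map; unknown headers are an error.
#'
#' @param path path to a CSV file with a header row.
#' @return data.frame with canonical column names (`name`, `mol_weight`,
#'   `alogp`, `rotatable_bonds`, `psa`, `hba`, `hbd`, `aromatic_rings`,
#'   optionally `ro5_violations`).
#' @export
loadMolecularProperties <- function(path) {
  if (!file.exists(path))
    stop("property table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  names(tab) <- .normalizeHeaders(names(tab), .MOLPROP_ALIASES,
                                  "molecular-property")
  tab
}

#' Read an ADMET profile table
#'
#' CSV with one compound per row and pkCSM-style pharmacokinetic and
#' toxicity columns (water solubility, Caco-2 permeability, intestinal
#' absorption, skin logKp, BBB logBB, CNS logPS, maximum tolerated dose,
#' hepatotoxicity, skin sensitization, T. pyriformis toxicity, minnow
#' log LC50). Common header variants are accepted via an alias map.
#'
#' @param path path to a CSV file with a header row.
#' @return data.frame with canonical column names.
#' @export
loadAdmetTable <- function(path) {
  if (!file.exists(path))
    stop("ADMET table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  names(tab) <- .normalizeHeaders(names(tab), .ADMET_ALIASES, "ADMET")
  tab
}

.requireFields <- function(tab, fields, what) {
  missing <- setdiff(fields, names(tab))
  if (length(missing))
    stop("missing ", what, " field(s): ", paste(missing, collapse = ", "))
}

#' Count Lipinski rule-of-five violations
#'
#' Counts, per compound, how many of the four rules are broken:
#' molecular weight > 500 Da, ALogP > 5, hydrogen-bond donors > 5,
#' hydrogen-bond acceptors > 10.
#'
#' @param props data.frame with columns `mol_weight`, `alogp`, `hbd`,
#'   `hba` (e.g. from [loadMolecularProperties()]).
#' @return integer vector of violation counts in 0..4, named by compound
#'   when a `name` column is present.
#' @examples
#' lipinskiViolations(data.frame(mol_weight = 458.38, alogp = 2.23,
#'                               hbd = 8, hba = 11))  # 2
#' @export
lipinskiViolations <- function(props) {
  .requireFields(props, c("mol_weight", "alogp", "hbd", "hba"),
                 "molecular-property")
  v <- (props$mol_weight > 500) + (props$alogp > 5) +
    (props$hbd > 5) + (props$hba > 10)
  v <- as.integer(v)
  if ("name" %in% names(props)) names(v) <- props$name
  v
}

#' Oral-bioavailability flags
#'
#' Pass/fail flags for the three heuristics beyond the rule of five:
#' seven or fewer rotatable bonds; twelve or fewer hydrogen-bond
#' acceptors and donors; at most three aromatic rings.
#'
#' @param props data.frame with columns `rotatable_bonds`, `hba`, `hbd`,
#'   `aromatic_rings` (counts, non-negative).
#' @return data.frame with logical columns `rotatable_ok`, `hbond_ok`,
#'   `rings_ok` (plus `name` when present).
#' @export
oralBioavailabilityFlags <- function(props) {
  .requireFields(props, c("rotatable_bonds", "hba", "hbd",
                          "aromatic_rings"), "molecular-property")
  counts <- props[c("rotatable_bonds", "hba", "hbd", "aromatic_rings")]
  if (any(unlist(counts) < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  out <- data.frame(
    rotatable_ok = props$rotatable_bonds <= 7,
    hbond_ok = props$hba <= 12 & props$hbd <= 12,
    rings_ok = props$aromatic_rings <= 3
  )
  if ("name" %in% names(props))
    out <- cbind(name = props$name, out)
  out
}

#' Classify an ADMET profile against fixed thresholds
#'
#' Applies one threshold rule per property, each a pure function of its
#' own field: Caco-2 permeability is `high` above 0.90; intestinal
#' absorption is `poor` below 30 percent, `adequate` otherwise; skin
#' permeability is `low-permeability` for logKp above -2.5; BBB
#' permeability is `readily-crosses` for logBB above 0.3,
#' `poorly-distributed` below -1, `intermediate` between; T. pyriformis
#' toxicity is `toxic` above -0.5 log ug/L; minnow toxicity is
#' `high-acute-toxicity` for log LC50 below -0.3. A missing value yields
#' `unknown` for that rule only.
#'
#' @param profile data.frame with (a subset of) the canonical ADMET
#'   columns; see [loadAdmetTable()].
#' @return data.frame of categorical labels, one row per compound, with
#'   columns `caco2`, `absorption`, `skin`, `bbb`, `tpyriformis`,
#'   `minnow` (plus `name` when present).
#' @export
classifyAdmet <- function(profile) {
  n <- nrow(profile)
  get <- function(col) {
    if (col %in% names(profile)) suppressWarnings(as.numeric(profile[[col]]))
    else rep(NA_real_, n)
  }
  lab <- function(x, f) ifelse(is.na(x), "unknown", f(x))
  caco2 <- get("caco2")
  absorption <- get("intestinal_absorption")
  skin <- get("skin_logkp")
  bbb <- get("bbb_logbb")
  tpyr <- get("tpyriformis")
  minnow <- get("minnow_loglc50")
  out <- data.frame(
    caco2 = lab(caco2, function(x) ifelse(x > 0.90, "high", "not-high")),
    absorption = lab(absorption,
                     function(x) ifelse(x < 30, "poor", "adequate")),
    skin = lab(skin, function(x)
      ifelse(x > -2.5, "low-permeability", "not-low")),
    bbb = lab(bbb, function(x)
      ifelse(x > 0.3, "readily-crosses",
             ifelse(x < -1, "poorly-distributed", "intermediate"))),
    tpyriformis = lab(tpyr,
                      function(x) ifelse(x > -0.5, "toxic", "non-toxic")),
    minnow = lab(minnow, function(x)
      ifelse(x < -0.3, "high-acute-toxicity", "not-high")),
    stringsAsFactors = FALSE
  )
  if ("name" %in% names(profile))
    out <- cbind(name = profile$name, out)
  out
}

#' Screen compounds on molecular properties and ADMET profiles
#'
#' Combines [lipinskiViolations()], [oralBioavailabilityFlags()] and
#' [classifyAdmet()] into one per-compound report. Either table may be
#' omitted; rows are matched by compound name when both are given.
#'
#' @param props molecular-property data.frame (canonical columns), or
#'   NULL.
#' @param admet ADMET data.frame (canonical columns), or NULL.
#' @return data.frame, one row per compound, with `ro5_violations`, the
#'   oral flags and the ADMET labels (columns present according to the
#'   inputs supplied).
#' @export
screenCompounds <- function(props = NULL, admet = NULL) {
  if (is.null(props) && is.null(admet))
    stop("at least one of props or admet must be supplied")
  rep_p <- NULL
  if (!is.null(props)) {
    if (nrow(props) == 0L) {
      rep_p <- data.frame(name = character(0))
    } else {
      rep_p <- oralBioavailabilityFlags(props)
      rep_p <- cbind(rep_p, ro5_violations = unname(lipinskiViolations(props)))
      if (!"name" %in% names(rep_p))
        rep_p <- cbind(name = as.character(seq_len(nrow(rep_p))), rep_p)
    }
  }
  rep_a <- NULL
  if (!is.null(admet)) {
    if (nrow(admet) == 0L) {
      rep_a <- data.frame(name = character(0))
    } else {
      rep_a <- classifyAdmet(admet)
      if (!"name" %in% names(rep_a))
        rep_a <- cbind(name = as.character(seq_len(nrow(rep_a))), rep_a)
    }
  }
  if (is.null(rep_a)) return(rep_p)
  if (is.null(rep_p)) return(rep_a)
  merge(rep_p, rep_a, by = "name", all = TRUE, sort = FALSE)
}
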