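#' CYP3A4/5 abundances for the two virtual genotype populations
#'
#' Hepatic (pmol/mg microsomal protein) and intestinal (nmol total gut
#' enzyme) CYP3A4 and CYP3A5 abundances of the Caucasian and Chinese
#' virtual populations, split by CYP3A5 genotype class. Non-expressers
#' (homozygous *3) carry zero functional CYP3A5 in liver and intestine.
#'
#' @return A tibble with columns `ethnicity`, `genotype_class`, `organ`,
#'   `isoform`, `abundance`.
#' @export
cyp3a_abundances <- function() {
  base <- tibble::tribble(
    ~ethnicity, ~organ, ~isoform, ~abundance,
    "caucasian", "liver", "CYP3A4", 137,
    "caucasian", "liver", "CYP3A5", 103,
    "caucasian", "gut", "CYP3A4", 66.2,
    "caucasian", "gut", "CYP3A5", 24.6,
    "chinese", "liver", "CYP3A4", 120,
    "chinese", "liver", "CYP3A5", 82,
    "chinese", "gut", "CYP3A4", 58,
    "chinese", "gut", "CYP3A5", 21.5
  )
  dplyr::bind_rows(
    dplyr::mutate(base, genotype_class = "expresser"),
    base |>
      dplyr::mutate(
        genotype_class = "non_expresser",
        abundance = ifelse(.data$isoform == "CYP3A5", 0, .data$abundance)
      )
  ) |>
    dplyr::relocate("genotype_class", .after = "ethnicity")
}

# representative-individual physiology per ethnicity; overridable through
# build_population(...). Flows are whole-blood flows in L/h, volumes in L.
default_physiology <- function(ethnicity) {
  switch(ethnicity,
    caucasian = list(
      body_mass_kg = 70,
      liver_mass_g = 1650,
      mppgl = 40,           # mg microsomal protein per g liver
      v_liver = 1.57,
      q_hepatic = 97,       # total hepatic blood flow
      q_villous = 18,       # mucosal/villous blood flow (portal fraction)
      v_enterocyte = 0.3,
      v_adipose = 14.2,
      q_adipose = 15.6,
      v_blood = 5.2,
      v_rest = 50,
      q_rest = 270,
      haematocrit = 0.45
    ),
    chinese = list(
      body_mass_kg = 63,
      liver_mass_g = 1500,
      mppgl = 40,
      v_liver = 1.43,
      q_hepatic = 90,
      q_villous = 17,
      v_enterocyte = 0.28,
      v_adipose = 11.5,
      q_adipose = 13,
      v_blood = 4.7,
      v_rest = 45,
      q_rest = 250,
      haematocrit = 0.42
    ),
    abort(sprintf("unknown ethnicity '%s'", ethnicity))
  )
}

#' Build a genotype-specific virtual population
#'
#' Assembles the CYP3A4/5 abundances and representative physiology of one
#' of the four virtual populations (Caucasian or Chinese, CYP3A5
#' expresser or non-expresser). Non-expressers have zero CYP3A5 in liver
#' and intestine; expressers carry the population-typical abundances.
#'
#' @param ethnicity `"chinese"` or `"caucasian"`.
#' @param genotype_class `"expresser"` or `"non_expresser"`.
#' @param physiology Optional named list overriding individual physiology
#'   entries (see [default_physiology] fields such as `liver_mass_g`,
#'   `mppgl`, `q_hepatic`).
#'
#' @return An object of class `cyp_population`: a list with `ethnicity`,
#'   `genotype_class`, `liver_abundance` and `gut_abundance` (named
#'   numeric vectors per isoform, pmol/mg and nmol respectively) and
#'   `physiology`.
#' @export
#' @examples
#' build_population("chinese", "expresser")$liver_abundance
build_population <- function(ethnicity = c("chinese", "caucasian"),
                             genotype_class = c("expresser", "non_expresser"),
                             physiology = list()) {
  ethnicity <- match.arg(ethnicity)
  genotype_class <- match.arg(genotype_class)
  ab <- cyp3a_abundances() |>
    dplyr::filter(
      .data$ethnicity == !!ethnicity,
      .data$genotype_class == !!genotype_class
    )
  phys <- utils::modifyList(default_physiology(ethnicity), physiology)
  pick <- function(org) {
    x <- ab[ab$organ == org, ]
    setNames(x$abundance, x$isoform)
  }
  structure(
    list(
      ethnicity = ethnicity,
      genotype_class = genotype_class,
      liver_abundance = pick("liver"),
      gut_abundance = pick("gut"),
      physiology = phys
    ),
    class = "cyp_population"
  )
}

#' Tacrolimus CYP3A enzyme kinetics
#'
#' Recombinant-enzyme Michaelis-Menten constants for the two modelled
#' tacrolimus metabolic pathways, 13-O-desmethyl tacrolimus (13-DMT) and
#' 12-hydroxy tacrolimus (12-HT), by isoform, with the inter-system
#' extrapolation factor (ISEF) reconciling recombinant activity with
#' liver microsomal activity.
#'
#' @return A tibble with columns `isoform`, `pathway`, `vmax`
#'   (pmol/min/pmol P450), `km_u` (unbound Michaelis constant, uM) and
#'   `isef`.
#' @export
tacrolimus_kinetics <- function() {
  tibble::tribble(
    ~isoform, ~pathway, ~vmax, ~km_u,
    "CYP3A4", "13-DMT", 8, 0.21,
    "CYP3A4", "12-HT", 0.6, 0.29,
    "CYP3A5", "13-DMT", 17, 0.21,
    "CYP3A5", "12-HT", 1.4, 0.35
  ) |>
    dplyr::mutate(isef = 0.24)
}

validate_enzyme_kinetics <- function(kinetics) {
  check_columns(kinetics, c("isoform", "pathway", "vmax", "km_u", "isef"),
                "enzyme kinetics")
  if (any(kinetics$vmax <= 0) || any(kinetics$km_u <= 0) ||
      any(kinetics$isef <= 0)) {
    abort("`vmax`, `km_u` and `isef` must all be positive")
  }
  dup <- kinetics |> dplyr::count(.data$isoform, .data$pathway)
  if (any(dup$n > 1)) abort("pathway names must be unique within isoform")
  invisible(kinetics)
}

#' Whole-liver unbound intrinsic clearance
#'
#' Scales per-pmol recombinant clearances to the whole organ:
#' \deqn{CL_{int,u} = \sum_{iso} \sum_{path} ISEF \cdot V_{max}/K_{m,u}
#'   \cdot abundance_{iso} \cdot MPPGL \cdot liver\ mass,}
#' converted from uL/min to L/h. Also reports each isoform's fractional
#' share of the total (the fm entering static DDI arithmetic when hepatic
#' CYP3A is the only elimination route).
#'
#' @param kinetics Enzyme kinetics tibble, e.g. [tacrolimus_kinetics()].
#' @param population A `cyp_population` from [build_population()].
#'
#' @return A list with `clint_l_h` (total unbound intrinsic clearance,
#'   L/h) and `shares` (tibble: `isoform`, `clint_l_h`, `share`).
#' @export
#' @examples
#' hepatic_clint_u(tacrolimus_kinetics(), build_population("chinese", "expresser"))
hepatic_clint_u <- function(kinetics, population) {
  validate_enzyme_kinetics(kinetics)
  phys <- population$physiology
  missing_iso <- setdiff(unique(kinetics$isoform),
                         names(population$liver_abundance))
  if (length(missing_iso) > 0) {
    abort(sprintf("no liver abundance for isoform(s): %s",
                  paste(missing_iso, collapse = ", ")))
  }
  shares <- kinetics |>
    dplyr::group_by(.data$isoform) |>
    dplyr::summarise(
      per_pmol_ul_min = sum(.data$isef * .data$vmax / .data$km_u),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      abundance = population$liver_abundance[.data$isoform],
      clint_l_h = .data$per_pmol_ul_min * .data$abundance *
        phys$mppgl * phys$liver_mass_g * 60 / 1e6
    )
  total <- sum(shares$clint_l_h)
  shares$share <- if (total > 0) shares$clint_l_h / total else 0
  list(
    clint_l_h = total,
    shares = dplyr::select(shares, "isoform", "clint_l_h", "share")
  )
}

#' Whole-gut unbound intrinsic clearance
#'
#' As [hepatic_clint_u()] but scaled by total intestinal enzyme content
#' (nmol) rather than microsomal protein density.
#'
#' @inheritParams hepatic_clint_u
#' @return A list with `clint_l_h` and per-isoform `shares`.
#' @export
gut_clint_u <- function(kinetics, population) {
  validate_enzyme_kinetics(kinetics)
  missing_iso <- setdiff(unique(kinetics$isoform),
                         names(population$gut_abundance))
  if (length(missing_iso) > 0) {
    abort(sprintf("no gut abundance for isoform(s): %s",
                  paste(missing_iso, collapse = ", ")))
  }
  shares <- kinetics |>
    dplyr::group_by(.data$isoform) |>
    dplyr::summarise(
      per_pmol_ul_min = sum(.data$isef * .data$vmax / .data$km_u),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      abundance_nmol = population$gut_abundance[.data$isoform],
      clint_l_h = .data$per_pmol_ul_min * .data$abundance_nmol * 1000 *
        60 / 1e6
    )
  total <- sum(shares$clint_l_h)
  shares$share <- if (total > 0) shares$clint_l_h / total else 0
  list(
    clint_l_h = total,
    shares = dplyr::select(shares, "isoform", "clint_l_h", "share")
  )
}
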