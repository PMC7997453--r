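# shared fixtures: coarse-grid simulation settings keep the suite fast
# while staying well inside solver accuracy for the asserted tolerances

fast_sim <- function(..., dt = 0.1) simulate_pk(..., dt = dt)

pop_expresser <- function() build_population("chinese", "expresser")
pop_nonexpresser <- function() build_population("chinese", "non_expresser")

# a population with no CYP3A anywhere: victim elimination switched off
pop_no_enzyme <- function() {
  pop <- pop_nonexpresser()
  pop$liver_abundance[] <- 0
  pop$gut_abundance[] <- 0
  pop
}

# victim amount columns of a profile (umol)
victim_amount_cols <- c("v_lum", "v_ent", "v_liv", "v_cen", "v_adi", "v_rob")

# printed Table-1-style verification pairs (predicted, observed) used by
# the fold-error arithmetic checks
table1_pairs <- function() {
  tibble::tribble(
    ~metric, ~predicted, ~observed, ~fe_printed,
    "cmax", 5.74, 3.88, 1.48,
    "cmax", 9.93, 5.52, 1.80,
    "cmax", 14.50, 14.09, 1.03,
    "cmax", 23.87, 24.28, 1.02,
    "cmax", 21.41, 20.8, 1.03,
    "cmax", 36.73, 27.90, 1.32,
    "auc", 22.50, 19.34, 1.16,
    "auc", 37.47, 30.34, 1.24,
    "auc", 71.53, 60.83, 1.18,
    "auc", 102.54, 119.02, 1.16,
    "auc", 131.07, 90.40, 1.45,
    "auc", 227.07, 134.77, 1.68
  )
}

# printed DDI AUC pairs whose printed ratio is self-consistent at 2 d.p.
table2_pairs <- function() {
  tibble::tribble(
    ~auc_alone, ~auc_with, ~aucr_printed,
    102.80, 152.07, 1.48,
    102.80, 154.70, 1.50,
    102.80, 195.23, 1.90,
    102.81, 156.70, 1.52,
    102.81, 233.02, 2.27,
    102.81, 247.91, 2.41,
    102.80, 113.25, 1.10,
    102.81, 142.93, 1.39,
    72.04, 127.91, 1.78,
    72.05, 134.10, 1.86,
    72.05, 126.94, 1.76,
    72.04, 156.05, 2.17,
    72.04, 73.20, 1.02,
    72.04, 80.99, 1.12,
    72.04, 82.24, 1.14,
    72.05, 73.20, 1.02,
    72.05, 111.45, 1.55,
    72.05, 112.85, 1.57
  )
}
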