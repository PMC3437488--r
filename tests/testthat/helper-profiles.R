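# shared fixture builders (all fixtures are generated in code)

six_bins <- function() impactor_bins()

profile <- function(conc, location = "indoor", state = "occupied",
                    analyte = "bacterial_genomes", bins = six_bins()) {
  concentration_profile(bins, conc, analyte = analyte, location = location,
                        state = state)
}

flat_loss_rates <- function(k, bins = six_bins()) {
  bin_loss_rates(bins, rep(k, nrow(bins)))
}

classroom_room <- function() {
  room_params(volume_m3 = 90, aer_per_h = 5.5, occupancy = 4.7)
}

# infiltration factors object without going through vacant profiles
make_f <- function(f, bins = six_bins()) {
  infiltration_factors(
    profile(f, "indoor", "vacant", bins = bins),
    profile(rep(1, length(f)), "outdoor", "vacant", bins = bins))
}
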