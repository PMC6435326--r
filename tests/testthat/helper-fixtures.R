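# Small builders used across test files.

make_record <- function(protein_id = "P1", peptide = "AASPK",
                        site_position = 3, residue = "S", glycoform = "Tn",
                        intensity_medium = 100, intensity_light = 100,
                        paired = TRUE) {
  data.frame(protein_id = protein_id, peptide = peptide,
             site_position = site_position, residue = residue,
             glycoform = glycoform, intensity_medium = intensity_medium,
             intensity_light = intensity_light, paired = paired,
             stringsAsFactors = FALSE)
}

# Records for one site with given PSM-level log10 ratios.
make_site_records <- function(ratios, protein_id = "P1", site_position = 3,
                              residue = "S", glycoform = "Tn") {
  do.call(rbind, lapply(ratios, function(r) {
    make_record(protein_id = protein_id, site_position = site_position,
                residue = residue, glycoform = glycoform,
                intensity_medium = 1000, intensity_light = 1000 * 10 ^ r)
  }))
}

straight_track <- function(n = 30, step = 1, dt = 40, dir = c(1, 0, 0)) {
  pos <- outer(0:(n - 1) * step, dir)
  track("straight", 0:(n - 1), (0:(n - 1)) * dt, pos)
}

stationary_track <- function(n = 12, dt = 40) {
  track("still", 0:(n - 1), (0:(n - 1)) * dt,
        matrix(5, nrow = n, ncol = 3))
}
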