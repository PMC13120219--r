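# shared fixtures, all built in code

make_table <- function(formulas, intensities, sample_id = "fix") {
  recs <- parse_formula(formulas)
  recs$intensity <- intensities
  formula_table(recs, sample_id = sample_id)
}

# two-record table: one lignin (intensity 3), one protein (intensity 1)
lignin_protein_table <- function() {
  # C10H12O6: O/C 0.6, H/C 1.2 -> lignins; C5H10NO2 invalid parity; use
  # C5H10O2? O/C 0.4 H/C 2.0 -> proteins window needs H/C in [1.5, 2.2)
  make_table(c("C10H12O6", "C5H10O2"), c(3, 1))
}

# small coarse-grid EEM stack for fast PARAFAC tests
small_stack <- function(n_samples = 12, refs = reference_components()[1:3],
                        noise_frac = 0, seed = 1) {
  gen_eem_stack(n_samples, refs, noise_frac = noise_frac, seed = seed,
                ex_grid = seq(240, 450, by = 10),
                em_grid = seq(250, 600, by = 5))
}

expect_setequal_chr <- function(a, b) expect_setequal(as.character(a), as.character(b))
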