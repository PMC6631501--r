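# Shared objects for the suite. The packaged chlorogenic-acid tables are
# small, so fitting once here keeps individual tests cheap.
cga_fit <- fit_quadratic(cga_runs())
cga_an <- rsm_anova(cga_fit)

# a tiny noise-free synthetic truth for closure tests (2 factors)
toy_factors <- dplyr::bind_rows(
  factor_spec("a", "u", center = 10, step = 2, symbol = "X1"),
  factor_spec("b", "v", center = 0, step = 5, symbol = "X2")
)
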