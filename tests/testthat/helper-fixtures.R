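# shared fixtures: all synthetic, built at test time

fix_windows <- default_windows()

# single-metabolite sample: isolated lactate peak plus TMSP
lactate_sample <- function(enrichment = 0.42, amount = 1,
                           tmsp_steady = 1.0) {
  sample_spec(amounts = c(Lactate = amount),
              enrichments = c(Lactate = enrichment),
              tmsp_steady_factor = tmsp_steady)
}

# full 17-metabolite sample at the packaged defaults
default_sample <- function(tmsp_steady = 1.10) {
  sample_spec(amounts = default_amounts(),
              enrichments = default_enrichments(),
              tmsp_steady_factor = tmsp_steady)
}

# identity copula over the default metabolites
identity_copula <- function() {
  mets <- names(default_enrichments())
  C <- diag(length(mets))
  dimnames(C) <- list(mets, mets)
  C
}

# copula with one planted pair
pair_copula <- function(a = "Lactate", b = "Ala", r = 0.92) {
  C <- identity_copula()
  C[a, b] <- C[b, a] <- r
  C
}

# analytic Lorentzian window integral, written out independently of the
# package implementation
analytic_area <- function(x0, gamma, lo, hi, area = 1) {
  area / pi * (atan((hi - x0) / gamma) - atan((lo - x0) / gamma))
}
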