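# internal helpers shared across modules

# normalize a stratum field: trim, collapse internal whitespace, lower-case
norm_field <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

# composite key identifying an equipment stratum (TPS, linac class, energy, MLC)
stratum_key <- function(tps, linac_class, beam_energy, mlc_model) {
  fields <- list(tps, linac_class, beam_energy, mlc_model)
  if (any(vapply(fields, function(f) any(!nzchar(trimws(f))), logical(1)))) {
    abort("all stratum fields (tps, linac_class, beam_energy, mlc_model) must be non-empty",
          class = "beamaudit_invalid")
  }
  paste(norm_field(tps), norm_field(linac_class),
        norm_field(beam_energy), norm_field(mlc_model), sep = "|")
}

check_finite <- function(x, what) {
  if (length(x) == 0 || any(!is.finite(x))) {
    abort(sprintf("%s must be non-empty and finite", what),
          class = "beamaudit_invalid")
  }
  invisible(x)
}

# deterministic per-unit substream seeds below 2^31, derived from one master
# seed so cohorts are reproducible under insertion of new institutions
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 100003) %% 2147483629L)
}

first_existing <- function(df, cols) cols[cols %in% names(df)][1]
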