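# Shared fixture builders for the test suite. Everything is generated
# in code; no binary fixtures.

# Noiseless simulated amplification curve.
quiet_curve <- function(N0, E0 = 1, ...) {
  simulate_amplification(amp_model(N0 = N0, E0 = E0, noise_sd = 0, ...))
}

# Melt profile from one or more true component Tm values.
profile_from_tms <- function(tms, target = "rbcL-LL", sample_id = "s",
                             amplitude = 1, width = 0.5, ...) {
  comps <- lapply(tms, melt_component, width = width, amplitude = amplitude)
  call_peaks(derivative_profile(
    simulate_melt(comps, sample_id = sample_id, target = target)), ...)
}

# Minimal hand-built melt profile (bypasses signal generation) for
# classification and summary tests where only the peak table matters.
fake_profile <- function(tms, target = "rbcL-LL", sample_id = "s") {
  np <- length(tms)
  peaks <- if (np) {
    data.frame(tm = sort(tms), height = rev(seq_len(np)),
               prominence = rev(seq_len(np)),
               is_major = seq_len(np) == 1L)
  } else data.frame(tm = numeric(0), height = numeric(0),
                    prominence = numeric(0), is_major = logical(0))
  if (np > 1L) {  # tallest first
    ord <- order(-peaks$height)
    peaks <- peaks[ord, ]
    peaks$is_major <- seq_len(np) == 1L
  }
  structure(list(sample_id = sample_id, target = target, peaks = peaks,
                 n_peaks = np,
                 profile_class = switch(as.character(min(np, 3L)),
                                        "0" = "none", "1" = "single",
                                        "2" = "double", "3" = "multi"),
                 taxon_call = NA_character_, taxon_flags = character(0)),
            class = "melt_profile")
}

# Long-format amplification table for two replicate wells of one sample.
amp_table_fixture <- function(N0 = 1e4, E0 = 1, sample_id = "s1",
                              target = "rnpB-HL") {
  rows <- lapply(c("A1", "A2"), function(w) {
    cv <- simulate_amplification(amp_model(N0 = N0, E0 = E0, noise_sd = 0),
                                 sample_id = sample_id, target = target,
                                 well = w)
    data.frame(well = w, sample_id = sample_id, target = target,
               cycle = cv$cycles, fluorescence = cv$fluorescence)
  })
  do.call(rbind, rows)
}

# The packaged survey Cp summary table.
survey_summary_fixture <- function() {
  read_cp_summary(system.file("extdata", "survey_cp_summary.csv",
                              package = "cladeqpcr"))
}
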