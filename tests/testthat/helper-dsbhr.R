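# Shared fixture builders (all in code; no stored binaries).

# Minimal hand-built gel table: one strain, control + one dose lane,
# intensities chosen so that F and N are exact round numbers.
make_manual_gel <- function() {
  bands <- data.frame(
    band_id = rep(c("b1", "b2", "b3"), 2),
    chromosomes = rep(c("c1", "c2", "c3"), 2),
    size_kb = rep(c(250, 1000, 1500), 2),
    lane_id = rep(c("control", "dose"), each = 3),
    intensity = c(100, 100, 100,
                  100 * exp(-1.4), 100 * exp(-5.6), 100 * exp(-8.4)),
    stringsAsFactors = FALSE
  )
  lanes <- data.frame(
    lane_id = c("control", "dose"),
    strain = "WT", dose_krad = c(0, 80), time_h = 0,
    is_control = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  gel_lane_table(bands, lanes)
}

# One-chromosome karyotype of the given size (Mb), for closed-form checks.
one_chrom_karyotype <- function(size_mb, ploidy = 1, replicated = FALSE) {
  karyotype(data.frame(name = "chr", size_mb = size_mb),
            ploidy = ploidy, replicated = replicated)
}
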