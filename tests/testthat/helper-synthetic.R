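# Shared fixtures, all built in code.

# noiseless, cardiac-free ground truth for deterministic round-trip checks
quiet_truth <- function(seed = 1, ...) {
  vot_ground_truth(cardiac = list(freq = 1.2, amp_nirs = 0, amp_bfi_frac = 0),
                   noise_sd = list(o2hb = 0, hhb = 0, bfi_frac = 0),
                   seed = seed, ...)
}

# small handmade recording: constant channels over a full protocol at
# reduced rates (cheap to build, still passes validation windows)
flat_recording <- function(fs_nirs = 10, fs_dcs = 7,
                           o2 = 43.6, hh = 24.9, bfi = 1.7e-9,
                           total = 660, t_inflate = 180, t_release = 480,
                           t_contract = t_inflate - 5) {
  vot_recording(
    list(channel_stream("O2HB", rep(o2, total * fs_nirs), fs = fs_nirs),
         channel_stream("HHB", rep(hh, total * fs_nirs), fs = fs_nirs),
         channel_stream("BFI", rep(bfi, floor(total * fs_dcs)), fs = fs_dcs)),
    cuff_events(t_inflate = t_inflate, t_release = t_release,
                end_time = total, t_contract = t_contract),
    subject_meta("flat", "climber"))
}

# lazily computed shared cohort (simulation + preprocessing + extraction is
# a few seconds; several test files reuse the same one)
.shared <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.shared$cohort)) {
    sim <- simulate_cohort(seed = 42)
    feats <- extract_cohort(lapply(sim$recordings, preprocess_recording))
    .shared$cohort <- list(sim = sim, features = feats)
  }
  .shared$cohort
}
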