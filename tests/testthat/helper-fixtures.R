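## Shared small fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

## Small ground truth + trials used by several files (64 px masks so the
## template geometry matches the generator's reference design).
small_truth <- function() {
  if (is.null(.fix$truth))
    .fix$truth <- ground_truth(n_voxels = 60, time_ms = seq(0, 400, 20), seed = 404)
  .fix$truth
}

small_trials <- function() {
  if (is.null(.fix$trials))
    .fix$trials <- simulate_trials(small_truth(), 300, seed = 405)
  .fix$trials
}

## Entropy of a discrete distribution in bits (independent oracle helper).
entropy_bits <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

## Plug-in MI from a 2-way probability table (independent oracle).
mi_table_bits <- function(pab) {
  entropy_bits(rowSums(pab)) + entropy_bits(colSums(pab)) - entropy_bits(pab)
}
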