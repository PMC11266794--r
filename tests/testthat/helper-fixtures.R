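# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures on disk.

# tiny deterministic lineage fixture: two division bands
tiny_lineage <- function() {
  lineage_spec(
    divisions = data.frame(row_index = c(40L, 90L), n_bars = c(1L, 3L)),
    image_height = 150L, image_width = 60L
  )
}

# merge a calls table with the simulator's ground truth, one row per animal
join_truth <- function(calls, truth) {
  merge(as.data.frame(unclass(calls)), truth, by = "individual_id",
        suffixes = c("", "_gt"))
}

# expected observed duration: the continuous duration discretized to the
# grid, minus one interval when a fragmentation bout consumed one quiescent
# observation; comparisons allow one-interval slack
expected_duration_min <- function(truth, interval_min = 20) {
  truth$duration_min - ifelse(truth$fragmented, interval_min, 0)
}
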