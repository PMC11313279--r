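# Classed conditions. Every error raised by this package carries class
# c("polytg_<what>", "polytg_error", "error", "condition") so callers (and the
# CLI) can branch on failure modes without parsing messages.

polytg_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(paste0("polytg_", class),
                                          "polytg_error")))
}

# failure classes used across modules:
#   not_abif, missing_record, malformed_directory  - abif_io
#   uninformative_position                         - trace_model
#   anchor_not_found, ambiguous_anchor             - tract_detection
#   empty_space                                    - genotype_model
#   no_matching_genotype, degenerate_observation   - scoring
#   invalid_spec                                   - synthetic
#   io, index_out_of_range                         - cli_report
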