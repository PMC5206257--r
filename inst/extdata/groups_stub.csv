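# Chemical-group memberships per compound are NOT part of the published
# results table (they were derived with a group-perception program not
# bundled here).  This stub documents the expected format: one row per
# compound, semicolon-separated group labels.  Fill in memberships from
# your own group-perception run to reproduce a group report on real data.
compound_id,groups
2,
3,
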