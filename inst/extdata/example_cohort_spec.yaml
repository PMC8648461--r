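# Cohort spec in the shape consumed by `elastoscore simulate --spec` and
# run_config()$cohort: per-arm patient counts at scores 1..5, pre and post
# drug administration, plus optional externally reported ("printed") group
# totals that summarize_cohort() audits against the counts.
# These are the default study distributions; edit counts to taste.
arms:
  experimental_crispr:
    pre: [1, 2, 3, 12, 7]
    post: [0, 1, 2, 13, 9]
  experimental_shrna:
    pre: [1, 3, 4, 14, 8]
    post: [1, 2, 3, 15, 9]
  control:
    pre: [3, 6, 5, 25, 14]
    post: [2, 1, 2, 27, 21]
printed_totals:
  experimental:
    pre: 217
    post: 224
  control:
    pre: 200
    post: 223
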