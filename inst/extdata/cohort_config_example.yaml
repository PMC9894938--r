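# Synthetic paired-cohort configuration schema.
# Keys mirror the arguments of recurdrift::cohort_config(); omitted keys
# take the package defaults shown here.
n_patients: 27            # PT-IBTR pairs
purity_range: [0.3, 0.9]  # per-sample tumor purity, uniform draw
depth_mean: 45            # mean reads per variant and per 10-kb bin
n_shared_variants: 100    # clonal trunk, present in both pair members
n_private_pt: 30          # private to the primary
n_private_ibtr: 60        # private to the recurrence
signature_mix_pt: null    # simplex over the signature matrix columns;
signature_mix_ibtr: null  # null = built-in defaults (0.7/0.3 vs 0.4/0.6)
cn_events: []             # list of {chrom, start, end, log2, sample, patient}
drift_sigma: 0.5          # sd of per-feature expression perturbation
germline_af_fraction: 0.1   # injected population-polymorphic contaminants
pon_artifact_fraction: 0.05 # injected recurrent artifacts (>=2 normals)
n_normals: 5              # simulated normal samples for the panel
n_rna: 500                # expression features
n_protein: 300            # protein features
coverage_noise_sd: 0.05   # fractional coverage noise per bin
seed: 1
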