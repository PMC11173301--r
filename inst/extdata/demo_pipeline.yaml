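# Demo pipeline: tabulated Stern-Volmer constants plus one generated
# dataset per analysis type. Run with:
#   Rscript inst/cli/bindspec run --config demo_pipeline.yaml --out out
seed: 17
out_dir: bindspec-report
datasets:
  - name: tabulated_constants
    analysis: [constants]
    constants:
      tau_ns: 5
      ksv:
        caf_low: 117050
        caf_high: 13780
        omc_low: 131160
        omc_high: 24690
  - name: two_site_titration
    analysis: [sv, segmented]
    generator:
      type: two_site
  - name: lehrer_titration
    analysis: [lehrer]
    generator:
      type: lehrer
  - name: cd_spectrum
    analysis: [cd]
    generator:
      type: cd
  - name: melt_curve
    analysis: [melt]
    generator:
      type: melt
      params:
        tm: 53.84
        noise_cv: 0.02
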