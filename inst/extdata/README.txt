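# Synthetic reference table (illustrative, not measured data)
#
# expression_ratios_synthetic.csv holds reporter activities constructed to
# carry the published qualitative strain contrasts (e.g. the 2.3-fold WT
# heat induction and the 3.7-fold cdc25/WT ratio at 25C) for use in
# examples and tests of compare_predictions(); the values are synthetic.
# Units mimic beta-galactosidase specific activity (nmol ONPG min-1 mg-1).
#
# pka_rn.model.json is the bundled model written by write_model_file();
# pka_strains.csv lists the strain library (deletions and level caps).
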