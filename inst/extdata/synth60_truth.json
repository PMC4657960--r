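{"variant":"PIR","lambda":0.5,"seed":42,"trips_per_origin":20000,"sparsify":{"type":"top_fraction","f":0.2},"note":"synthetic fixture generated by simulate_scenario(synthetic_config(seed = 42))"}
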