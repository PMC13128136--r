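# Example configuration: shallow-source chemotaxis run at reduced resolution.
# Any key omitted here falls back to the package default; unknown keys are
# rejected. See ?default_config for the full schema.
grid:
  M: 99
run:
  t_migrate: 2500
force:
  mode: chem
  mu_c: 0.045
chemo:
  provenance: geometry
  scale_factor: 0.1
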