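# Example simulation configuration: a quick 40 x 40 um scene.
# Load with read_sim_config(); unspecified fields take package defaults.
box_side: 40.0
n_agents: 480
eps_fraction: 0.25
n_steps: 40
burn_in: 300
pixel_size: 0.25
seed: 7
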