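# Baseline run configuration: six-monomer oligomer chain.
delta: 1.0      # net monomer reproduction rate per step
gamma: 100.0    # monomer carrying capacity
n: 6            # monomers per oligomer
K: [0.01, 0.02, 0.03, 0.04, 0.05]   # K1..K5 reaction constants
M0: [10, 0, 0, 0, 0]                # initial abundances (monomers only)
T: 200
seed: 1
mode: interacting
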