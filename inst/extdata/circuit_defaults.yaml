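# Standard simulation parameter set of the delayed Hes/ID/proneural circuit.
# Rates per minute, concentrations in molecules per cell, times in minutes.
# Degradation rates are derived on read as log(2) / half_life.
m0: 200.0                    # Hes transcription rate, mRNA/min (upper limit from the 2^12 RPM ceiling)
p0: 0.05                     # Hes translation rate, protein per mRNA per min (calibrated: 2-3 h oscillation)
hes_mrna_half_life: 24.0     # min
hes_protein_half_life: 22.0  # min (monomer, homodimer and heterodimer alike)
k: 0.001                     # dimerization rate, per molecule per min (homo- and heterodimer)
t_i: 19.0                    # intronic maturation delay, min (alternate pairing: 25 with n = 4)
n: 5.0                       # Hill coefficient
h0: 200.0                    # Hill factor, molecules (shared by all Hill terms)
eps: 0.5                     # Hes-ID repression efficiency relative to Hes-Hes
f: 0.0                       # auto-repression factor (0 = complete repression)
ID: 0.0                      # constant free-ID pool, molecules
I: 500.0                     # constant Notch input, molecules
ma0: 200.0                   # proneural transcription rate, mRNA/min
pa0: 0.05                    # proneural translation rate (matches p0)
proneural_half_life: 24.0    # min, all proneural species
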