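# J-coupling network of disodium [1-13C]fumarate in D2O.
# Spin order: 1 = Ha, 2 = Hb (the two vinylic protons), 3 = C1 (13C label).
# Values (Hz) transcribed from the hyperpolarized-fumarate literature
# (three-bond HH coupling across the double bond; two- and three-bond CH
# couplings to the labelled carboxylate carbon).
isotopes: ["1H", "1H", "13C"]
j_couplings:
  - pair: [1, 2]
    value_hz: 15.7
    note: 3J(Ha,Hb), trans olefinic
  - pair: [1, 3]
    value_hz: 3.2
    note: 2J(Ha,C1)
  - pair: [2, 3]
    value_hz: 6.6
    note: 3J(Hb,C1)
offsets_hz: [0, 0, 0]
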