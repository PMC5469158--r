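# Bundled substitution model matrices

Plain-text PAML `.dat` files (19 lower-triangular exchangeability rows, a
blank line, 20 equilibrium frequencies in residue order
A R N D C Q E G H I L K M F P S T W Y V). The numeric values are the
published matrices as distributed with standard phylogenetics software:

- `LG.dat` — Le & Gascuel (2008), Mol Biol Evol 25:1307-1320.
- `WAG.dat` — Whelan & Goldman (2001), Mol Biol Evol 18:691-699.
- `mtREV.dat` — the mtREV24 matrix of Adachi & Hasegawa (1996),
  J Mol Evol 42:459-468.
- `mtArt.dat` — Abascal, Posada & Zardoya (2007), Mol Biol Evol 24:1-5.
- `mtZoa.dat` — Rota-Stabelli, Yang & Telford (2009),
  Mol Phylogenet Evol 52:268-272.

Sanity anchors checked by the test suite: LG A-R = 0.425093,
WAG A-R = 0.551571, LG pi_A = 0.079066; frequencies of every file sum
to 1 within 1e-8.
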