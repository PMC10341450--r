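# Corner-residue definitions of the two proton-uptake channels of
# Cytochrome c Oxidase (core subunits: chain A = subunit I, chain B =
# subunit II), plus the Calpha pairs used as K-channel width measures and
# the key residues entering hydrogen-bond and connectivity analyses.
channels:
  D:
    name: D
    corners:
      - {chain: A, resid: 24,  resname: THR}
      - {chain: A, resid: 33,  resname: TYR}
      - {chain: A, resid: 109, resname: PHE}
      - {chain: A, resid: 110, resname: VAL}
      - {chain: A, resid: 121, resname: ASN}
      - {chain: A, resid: 132, resname: ASP}
      - {chain: A, resid: 136, resname: PRO}
      - {chain: A, resid: 138, resname: MET}
      - {chain: A, resid: 139, resname: ASN}
      - {chain: A, resid: 142, resname: SER}
      - {chain: A, resid: 197, resname: SER}
      - {chain: A, resid: 200, resname: SER}
      - {chain: A, resid: 201, resname: SER}
      - {chain: A, resid: 207, resname: ASN}
      - {chain: A, resid: 282, resname: PHE}
      - {chain: A, resid: 286, resname: GLU}
      - {chain: A, resid: 289, resname: ILE}
    key_residues:
      - {chain: A, resid: 26,  label: H26}
      - {chain: A, resid: 121, label: N121}
      - {chain: A, resid: 132, label: D132}
      - {chain: A, resid: 139, label: N139}
      - {chain: A, resid: 286, label: E286}
  K:
    name: K
    corners:
      - {chain: A, resid: 227, resname: LEU}
      - {chain: A, resid: 238, resname: LEU}
      - {chain: A, resid: 284, resname: HIS}
      - {chain: A, resid: 287, resname: VAL}
      - {chain: A, resid: 315, resname: PRO}
      - {chain: A, resid: 324, resname: GLY}
      - {chain: A, resid: 327, resname: GLY}
      - {chain: A, resid: 356, resname: ALA}
      - {chain: A, resid: 363, resname: ILE}
      - {chain: A, resid: 365, resname: SER}
      - {chain: A, resid: 366, resname: TRP}
      - {chain: A, resid: 398, resname: GLY}
      - {chain: B, resid: 96,  resname: HIS}
      - {chain: B, resid: 100, resname: LEU}
      - {chain: B, resid: 101, resname: GLU}
    width_pairs:
      - {chain_a: A, resid_a: 358, chain_b: A, resid_b: 319}
      - {chain_a: A, resid_a: 316, chain_b: A, resid_b: 362}
      - {chain_a: A, resid_a: 315, chain_b: B, resid_b: 101}
      - {chain_a: A, resid_a: 315, chain_b: A, resid_b: 365}
    key_residues:
      - {chain: A, resid: 288, label: Y288}
      - {chain: A, resid: 359, label: T359}
      - {chain: A, resid: 362, label: K362}
      - {chain: A, resid: 365, label: S365}
      - {chain: B, resid: 96,  label: H96}
      - {chain: B, resid: 101, label: E101}
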