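# Donor/acceptor atom tables per residue type (CHARMM naming).  Each donor
# entry pairs a heavy atom with its polar hydrogens; acceptors are heavy
# atoms with lone pairs.  Protonated acid side chains (ASPP/GLUP) gain the
# carboxyl OH donor.  Edit or extend freely; synthetic probe residues (PRB)
# and the hydronium ion (H3O) are included so toy systems run unchanged.
TIP3: {donors: [{d: OH2, h: [H1, H2]}], acceptors: [OH2]}
HOH:  {donors: [{d: O,   h: [H1, H2]}], acceptors: [O]}
WAT:  {donors: [{d: O,   h: [H1, H2]}], acceptors: [O]}
SOL:  {donors: [{d: OW,  h: [HW1, HW2]}], acceptors: [OW]}
H3O:  {donors: [{d: OH2, h: [H1, H2, H3]}], acceptors: []}
SER:  {donors: [{d: OG,  h: [HG1]}], acceptors: [OG]}
THR:  {donors: [{d: OG1, h: [HG1]}], acceptors: [OG1]}
TYR:  {donors: [{d: OH,  h: [HH]}],  acceptors: [OH]}
LYS:  {donors: [{d: NZ,  h: [HZ1, HZ2, HZ3]}], acceptors: []}
ASP:  {donors: [], acceptors: [OD1, OD2]}
ASPP: {donors: [{d: OD2, h: [HD2]}], acceptors: [OD1, OD2]}
GLU:  {donors: [], acceptors: [OE1, OE2]}
GLUP: {donors: [{d: OE2, h: [HE2]}], acceptors: [OE1, OE2]}
ASN:  {donors: [{d: ND2, h: [HD21, HD22]}], acceptors: [OD1]}
GLN:  {donors: [{d: NE2, h: [HE21, HE22]}], acceptors: [OE1]}
HSD:  {donors: [{d: ND1, h: [HD1]}], acceptors: [NE2]}
HSE:  {donors: [{d: NE2, h: [HE2]}], acceptors: [ND1]}
HIS:  {donors: [{d: ND1, h: [HD1]}], acceptors: [NE2]}
PRB:  {donors: [{d: O,   h: [H1]}], acceptors: [O]}
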