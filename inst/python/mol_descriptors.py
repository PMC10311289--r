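#!/usr/bin/env python
"""Batch molecular descriptors for the R package.

Reads SMILES (one per line) from argv[1], writes a TSV to argv[2] with
columns: smiles, valid, qed, sa, logp, tpsa, mw, fp (hex-encoded 2048-bit
Morgan radius-2 fingerprint).  Invalid SMILES get valid=0 and empty fields.
"""
import sys
import os

from rdkit import Chem, RDLogger
from rdkit.Chem import QED, Descriptors, AllChem, RDConfig

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

RDLogger.DisableLog("rdApp.*")

FP_BITS = 2048
FP_RADIUS = 2


def fp_hex(mol):
    bv = AllChem.GetMorganFingerprintAsBitVect(mol, FP_RADIUS, nBits=FP_BITS)
    bits = bytearray(FP_BITS // 8)
    for b in bv.GetOnBits():
        bits[b // 8] |= 1 << (b % 8)
    return bits.hex()


def main():
    inp, out = sys.argv[1], sys.argv[2]
    with open(inp) as fh:
        smiles = [line.strip() for line in fh if line.strip()]
    with open(out, "w") as fh:
        fh.write("smiles\tvalid\tqed\tsa\tlogp\ttpsa\tmw\tfp\n")
        for s in smiles:
            mol = Chem.MolFromSmiles(s)
            if mol is None:
                fh.write(f"{s}\t0\t\t\t\t\t\t\n")
                continue
            fh.write("\t".join([
                s, "1",
                f"{QED.qed(mol):.10g}",
                f"{sascorer.calculateScore(mol):.10g}",
                f"{Descriptors.MolLogP(mol):.10g}",
                f"{Descriptors.TPSA(mol):.10g}",
                f"{Descriptors.MolWt(mol):.10g}",
                fp_hex(mol),
            ]) + "\n")


if __name__ == "__main__":
    main()
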