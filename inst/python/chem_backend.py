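#!/usr/bin/env python
"""Small-molecule library backend.

Parses SMILES / SDF V2000 files with RDKit and emits a JSON description of
each molecule: molecular weight, formal charge, heavy-atom list with
aggregated Gasteiger partial charges, bond list, rotatable torsions and
seeded 3D conformers (heavy atoms only).  Hydrogens are used internally for
charge assignment and embedding, then stripped; each hydrogen's partial
charge is folded into its parent heavy atom so downstream scoring can run
heavy-atom-only.

Usage:
    python chem_backend.py INPUT OUTPUT --seed 1 --nconfs 1 [--protonate]
"""

import argparse
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors

RDLogger.DisableLog("rdApp.*")

CARBOXYLIC_ACID = Chem.MolFromSmarts("[CX3](=O)[OX2H1]")
ALIPHATIC_AMINE = Chem.MolFromSmarts("[NX3;H2,H1,H0;!$(NC=O);!$(N=*);!$(N[O,S]);!a;$(N[CX4])]")


def protonate_ph74(mol):
    """Crude pH 7.4 rules: deprotonate carboxylic acids, protonate
    aliphatic amines.  Returns a sanitized copy."""
    rw = Chem.RWMol(mol)
    for match in rw.GetSubstructMatches(CARBOXYLIC_ACID):
        o = rw.GetAtomWithIdx(match[2])
        if o.GetFormalCharge() == 0:
            o.SetFormalCharge(-1)
            o.SetNumExplicitHs(0)
            o.SetNoImplicit(True)
    for match in rw.GetSubstructMatches(ALIPHATIC_AMINE):
        n = rw.GetAtomWithIdx(match[0])
        if n.GetFormalCharge() == 0 and n.GetTotalNumHs() + n.GetDegree() <= 3:
            n.SetFormalCharge(1)
            n.SetNumExplicitHs(n.GetTotalNumHs() + 1)
    out = rw.GetMol()
    Chem.SanitizeMol(out)
    return out


def rotatable_torsions(mol_h, heavy_map):
    """Rotatable bonds among heavy atoms; for each, the smaller fragment is
    the moving set.  Indices are 1-based positions in the heavy-atom list."""
    patt = Chem.MolFromSmarts("[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]")
    torsions = []
    for i, j in mol_h.GetSubstructMatches(patt):
        em = Chem.RWMol(mol_h)
        em.RemoveBond(i, j)
        frags = Chem.GetMolFrags(em.GetMol(), sanitizeFrags=False)
        side_j = next(f for f in frags if j in f)
        side_i = next(f for f in frags if i in f)
        if len(side_j) <= len(side_i):
            axis, moving = (i, j), side_j
        else:
            axis, moving = (j, i), side_i
        moving_heavy = [heavy_map[a] for a in moving if a in heavy_map]
        if axis[0] in heavy_map and axis[1] in heavy_map and len(moving_heavy) > 1:
            torsions.append({
                "axis": [heavy_map[axis[0]], heavy_map[axis[1]]],
                "moving": sorted(moving_heavy),
            })
    return torsions


def describe(mol, mol_id, seed, nconfs):
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = int(seed) & 0x7FFFFFFF
    cids = AllChem.EmbedMultipleConfs(mol, numConfs=nconfs, params=params)
    if len(cids) == 0:
        params.useRandomCoords = True
        cids = AllChem.EmbedMultipleConfs(mol, numConfs=nconfs, params=params)
    if len(cids) == 0:
        return None
    AllChem.ComputeGasteigerCharges(mol)

    heavy_map = {}          # rdkit idx -> 1-based heavy index
    elements, charges = [], []
    for atom in mol.GetAtoms():
        if atom.GetAtomicNum() == 1:
            continue
        heavy_map[atom.GetIdx()] = len(elements) + 1
        q = float(atom.GetDoubleProp("_GasteigerCharge"))
        for nb in atom.GetNeighbors():
            if nb.GetAtomicNum() == 1:
                q += float(nb.GetDoubleProp("_GasteigerCharge"))
        elements.append(atom.GetSymbol())
        charges.append(round(q, 5))

    bonds = []
    for b in mol.GetBonds():
        a1, a2 = b.GetBeginAtomIdx(), b.GetEndAtomIdx()
        if a1 in heavy_map and a2 in heavy_map:
            bonds.append([heavy_map[a1], heavy_map[a2]])

    confs = []
    for cid in cids:
        c = mol.GetConformer(cid)
        confs.append([
            [round(v, 4) for v in (c.GetAtomPosition(idx).x,
                                   c.GetAtomPosition(idx).y,
                                   c.GetAtomPosition(idx).z)]
            for idx in sorted(heavy_map, key=heavy_map.get)
        ])

    noH = Chem.RemoveHs(mol)
    return {
        "id": mol_id,
        "smiles": Chem.MolToSmiles(noH),
        "mw": round(Descriptors.MolWt(mol), 4),
        "formal_charge": Chem.GetFormalCharge(mol),
        "n_hydrogens": sum(1 for a in mol.GetAtoms() if a.GetAtomicNum() == 1),
        "heavy_atom_count": len(elements),
        "elements": elements,
        "charges": charges,
        "bonds": bonds,
        "torsions": rotatable_torsions(mol, heavy_map),
        "conformers": confs,
    }


def iter_input(path):
    if path.lower().endswith((".sdf", ".mol")):
        supplier = Chem.SDMolSupplier(path, removeHs=False)
        for k, mol in enumerate(supplier):
            name = None
            if mol is not None and mol.HasProp("_Name") and mol.GetProp("_Name").strip():
                name = mol.GetProp("_Name").strip().split()[0]
            yield mol, name or f"mol{k + 1}"
    else:
        with open(path) as fh:
            k = 0
            for line in fh:
                line = line.strip()
                if not line or line.startswith("#"):
                    continue
                k += 1
                parts = line.split(None, 1)
                smiles = parts[0]
                name = parts[1].strip().split()[0] if len(parts) > 1 else f"mol{k}"
                yield Chem.MolFromSmiles(smiles), name


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("input")
    ap.add_argument("output")
    ap.add_argument("--seed", type=int, default=1)
    ap.add_argument("--nconfs", type=int, default=1)
    ap.add_argument("--protonate", action="store_true")
    args = ap.parse_args()

    records, n_skipped = [], 0
    for k, (mol, mol_id) in enumerate(iter_input(args.input)):
        if mol is None:
            n_skipped += 1
            continue
        try:
            if args.protonate:
                mol = protonate_ph74(mol)
            rec = describe(mol, mol_id, seed=args.seed + 7919 * k, nconfs=args.nconfs)
        except Exception:
            rec = None
        if rec is None:
            n_skipped += 1
        else:
            records.append(rec)

    with open(args.output, "w") as fh:
        json.dump({"n_skipped": n_skipped, "molecules": records}, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main())
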