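"""Batch chemistry backend for the dilinet R package.

Reads a JSON request {"op": ..., "smiles": [...], "options": {...}} and
writes a JSON response. One process handles one batch; the R side invokes
it via system2() so that nothing here depends on the calling session.

Ops:
  standardize  -- filter / standardize / protonate / key14 for raw SMILES
  features     -- Morgan-2048(r2), MACCS-166, 2D descriptor catalogue,
                  15 physicochemical parameters for standardized SMILES
  match        -- SMARTS substructure matching (optionally matched atoms)
  validate     -- does each SMILES parse
"""

import json
import math
import sys
from collections import Counter

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, Lipinski, MACCSkeys, rdFingerprintGenerator
from rdkit.Chem import rdMolDescriptors
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")

CATALOGUE_VERSION = "rdkit-" + Chem.rdBase.rdkitVersion

# Organic subset + metalloids + noble gases; everything else is a metal.
_NONMETALS = {1, 2, 5, 6, 7, 8, 9, 10, 14, 15, 16, 17, 18, 32, 33, 34, 35, 36,
              52, 53, 54, 85, 86}


def _is_metal(atom):
    return atom.GetAtomicNum() not in _NONMETALS


_MD = rdMolStandardize.MetalDisconnector()
_NORM = rdMolStandardize.Normalizer()
_REION = rdMolStandardize.Reionizer()
_UNCHG = rdMolStandardize.Uncharger()
_TAUT = rdMolStandardize.TautomerEnumerator()
_MORGAN = rdFingerprintGenerator.GetMorganGenerator(radius=2, fpSize=2048)


class Reject(Exception):
    def __init__(self, reason):
        self.reason = reason


def _principal_fragment(mol):
    """Largest organic fragment; distinct tied organics -> ambiguous."""
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) == 1:
        return frags[0]
    organic = [f for f in frags
               if any(a.GetAtomicNum() == 6 for a in f.GetAtoms())]
    if not organic:
        if all(_is_metal(a) for f in frags for a in f.GetAtoms()
               if a.GetAtomicNum() > 1):
            raise Reject("metals_only")
        raise Reject("no_carbon")
    counts = [f.GetNumHeavyAtoms() for f in organic]
    top = max(counts)
    tied = [f for f, c in zip(organic, counts) if c == top]
    if len(tied) > 1:
        smis = {Chem.MolToSmiles(f) for f in tied}
        if len(smis) > 1:
            raise Reject("disconnected")
    return tied[0]


def _standardize_once(mol):
    mol = _MD.Disconnect(mol)
    mol = _NORM.normalize(mol)
    mol = _REION.reionize(mol)
    mol = _principal_fragment(mol)
    Chem.SanitizeMol(mol)
    mol = _UNCHG.uncharge(mol)
    for atom in mol.GetAtoms():
        atom.SetIsotope(0)
    Chem.RemoveStereochemistry(mol)
    mol = _TAUT.Canonicalize(mol)
    return mol


def _standardize(smiles, max_iter=5):
    """Iterate the standardization sequence to a SMILES fixpoint (<=5)."""
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        raise Reject("parse_failure")
    if not any(a.GetAtomicNum() == 6 for a in mol.GetAtoms()):
        heavy = [a for a in mol.GetAtoms() if a.GetAtomicNum() > 1]
        if heavy and all(_is_metal(a) for a in heavy):
            raise Reject("metals_only")
        raise Reject("no_carbon")
    history = []
    prev = Chem.MolToSmiles(mol)
    for _ in range(max_iter):
        mol = _standardize_once(mol)
        cur = Chem.MolToSmiles(mol)
        history.append(cur)
        if cur == prev:
            break
        prev = cur
        mol = Chem.MolFromSmiles(cur)
        if mol is None:
            raise Reject("parse_failure")
    else:
        # no fixpoint: most frequent iterate, ties lexicographically smallest
        counts = Counter(history)
        best = max(counts.values())
        cur = min(s for s, c in counts.items() if c == best)
        mol = Chem.MolFromSmiles(cur)
    if not any(a.GetAtomicNum() == 6 for a in mol.GetAtoms()):
        raise Reject("no_carbon")
    if Descriptors.MolWt(mol) > 1500.0:
        raise Reject("mw_over_1500")
    return mol


def _apply_pka_rules(mol, rules):
    """Rule-based dominant microstate at pH 7.0.

    Each rule: {name, type: acid|base, smarts, pka, atom, max_sites}.
    Acids with pKa < 7 are deprotonated at the matched atom; bases with
    pKa > 7 are protonated. Applied in table order; an atom is modified
    at most once.
    """
    rw = Chem.RWMol(mol)
    done = set()
    for rule in rules:
        typ = rule["type"]
        pka = float(rule["pka"])
        if typ == "acid" and pka >= 7.0:
            continue
        if typ == "base" and pka <= 7.0:
            continue
        patt = Chem.MolFromSmarts(rule["smarts"])
        if patt is None:
            continue
        max_sites = int(rule.get("max_sites", 0))
        nsites = 0
        for match in rw.GetMol().GetSubstructMatches(patt):
            idx = match[int(rule["atom"])]
            if idx in done:
                continue
            atom = rw.GetAtomWithIdx(idx)
            if typ == "acid":
                if atom.GetTotalNumHs() < 1 or atom.GetFormalCharge() != 0:
                    continue
                atom.SetFormalCharge(-1)
                atom.SetNumExplicitHs(atom.GetTotalNumHs() - 1)
                atom.SetNoImplicit(True)
            else:
                if atom.GetFormalCharge() != 0:
                    continue
                atom.SetNumExplicitHs(atom.GetTotalNumHs() + 1)
                atom.SetNoImplicit(True)
                atom.SetFormalCharge(1)
            done.add(idx)
            nsites += 1
            if max_sites and nsites >= max_sites:
                break
    out = rw.GetMol()
    try:
        Chem.SanitizeMol(out)
    except Exception:
        return None
    return out


def op_standardize(req):
    opts = req.get("options", {})
    protonate = bool(opts.get("protonate", True))
    rules = opts.get("pka_rules", [])
    out = []
    for smi in req["smiles"]:
        rec = {"smiles_std": None, "smiles_ph7": None, "key14": None,
               "mw": None, "rejected": True, "reject_reason": "none"}
        try:
            if not isinstance(smi, str) or not smi.strip():
                raise Reject("parse_failure")
            mol = _standardize(smi.strip())
            std = Chem.MolToSmiles(mol)
            rec["mw"] = Descriptors.MolWt(mol)
            ph7 = std
            if protonate and rules:
                pmol = _apply_pka_rules(mol, rules)
                if pmol is not None:
                    cand = Chem.MolToSmiles(pmol)
                    if Chem.MolFromSmiles(cand) is not None:
                        ph7 = cand
            key = Chem.inchi.MolToInchiKey(Chem.MolFromSmiles(ph7))
            if not key or len(key) < 14:
                raise Reject("parse_failure")
            rec.update(smiles_std=std, smiles_ph7=ph7, key14=key[:14],
                       rejected=False)
        except Reject as e:
            rec["reject_reason"] = e.reason
        except Exception:
            rec["reject_reason"] = "parse_failure"
        out.append(rec)
    return {"records": out}


def _num_ring_systems(mol):
    """Assembled (fused-counted-once) ring systems."""
    ri = mol.GetRingInfo()
    systems = []
    for ring in ri.AtomRings():
        ring = set(ring)
        merged = [s for s in systems if s & ring]
        for s in merged:
            systems.remove(s)
            ring |= s
        systems.append(ring)
    return len(systems)


def _physchem15(mol):
    return [
        Descriptors.TPSA(mol),
        float(Lipinski.NumHAcceptors(mol)),
        float(Lipinski.NumHDonors(mol)),
        Descriptors.FractionCSP3(mol),
        Descriptors.MolLogP(mol),
        float(Descriptors.NumRotatableBonds(mol)),
        float(rdMolDescriptors.CalcNumRings(mol)),
        float(_num_ring_systems(mol)),
        float(Descriptors.NumAromaticRings(mol)),
        float(rdMolDescriptors.CalcNumHeteroatoms(mol)),
        float(len(Chem.FindMolChiralCenters(
            mol, includeUnassigned=True, useLegacyImplementation=False))),
        float(sum(1 for a in mol.GetAtoms() if a.GetFormalCharge() > 0)),
        float(sum(1 for a in mol.GetAtoms() if a.GetFormalCharge() < 0)),
        float(Lipinski.NHOHCount(mol)),
        float(Lipinski.NOCount(mol)),
    ]


PHYSCHEM15_NAMES = [
    "TPSA", "NumHAcceptors", "NumHDonors", "FractionCSP3", "MolLogP",
    "NumRotatableBonds", "RingCount", "NumRingSystems", "NumAromaticRings",
    "NumHeteroatoms", "NumStereocenters", "NumPosCharged", "NumNegCharged",
    "NHOHCount", "NOCount",
]


def _clean(x):
    if x is None:
        return None
    try:
        x = float(x)
    except (TypeError, ValueError):
        return None
    if math.isnan(x) or math.isinf(x):
        return None
    return x


def op_features(req):
    opts = req.get("options", {})
    which = set(opts.get("which", ["morgan", "maccs", "descriptors",
                                   "physchem15"]))
    desc_names = [n for n, _ in Descriptors.descList]
    out = {"ok": [], "catalogue_version": CATALOGUE_VERSION}
    if "morgan" in which:
        out["morgan"] = []
    if "maccs" in which:
        out["maccs"] = []
    if "descriptors" in which:
        out["descriptor_names"] = desc_names
        out["descriptors"] = []
    if "physchem15" in which:
        out["physchem15_names"] = PHYSCHEM15_NAMES
        out["physchem15"] = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi) if isinstance(smi, str) else None
        if mol is None:
            out["ok"].append(False)
            for k in ("morgan", "maccs", "descriptors", "physchem15"):
                if k in out:
                    out[k].append(None)
            continue
        out["ok"].append(True)
        if "morgan" in which:
            fp = _MORGAN.GetFingerprint(mol)
            out["morgan"].append(sorted(fp.GetOnBits()))
        if "maccs" in which:
            fp = MACCSkeys.GenMACCSKeys(mol)
            # bit 0 of the 167-bit RDKit vector is unused; report keys 1..166
            out["maccs"].append([b - 1 for b in fp.GetOnBits() if b >= 1])
        if "descriptors" in which:
            vals = []
            for name, fn in Descriptors.descList:
                try:
                    vals.append(_clean(fn(mol)))
                except Exception:
                    vals.append(None)
            out["descriptors"].append(vals)
        if "physchem15" in which:
            try:
                out["physchem15"].append([_clean(v) for v in _physchem15(mol)])
            except Exception:
                out["physchem15"].append(None)
    return out


def op_match(req):
    opts = req.get("options", {})
    with_atoms = bool(opts.get("with_atoms", False))
    patterns = [Chem.MolFromSmarts(p) for p in opts.get("patterns", [])]
    hits, atoms = [], []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi) if isinstance(smi, str) else None
        row, arow = [], []
        for patt in patterns:
            if mol is None or patt is None:
                row.append(None)
                arow.append(None)
            else:
                m = mol.GetSubstructMatch(patt)
                row.append(1 if m else 0)
                arow.append(list(m) if m else [])
        hits.append(row)
        atoms.append(arow)
    out = {"hits": hits}
    if with_atoms:
        out["atoms"] = atoms
    return out


def op_maccs_highlight(req):
    """Map MACCS keys (1..166) back to matching atoms for highlighting."""
    opts = req.get("options", {})
    keys = [int(k) for k in opts.get("keys", [])]
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi) if isinstance(smi, str) else None
        row = []
        for k in keys:
            smarts, _ = MACCSkeys.smartsPatts.get(k, (None, 0))
            entry = {"key": k, "smarts": smarts, "atoms": None}
            if mol is not None and smarts and smarts != "?":
                patt = Chem.MolFromSmarts(smarts)
                if patt is not None:
                    m = mol.GetSubstructMatch(patt)
                    entry["atoms"] = list(m) if m else []
            row.append(entry)
        out.append(row)
    return {"highlights": out}


def op_validate(req):
    return {"ok": [Chem.MolFromSmiles(s) is not None
                   if isinstance(s, str) else False
                   for s in req["smiles"]]}


OPS = {"standardize": op_standardize, "features": op_features,
       "match": op_match, "validate": op_validate,
       "maccs_highlight": op_maccs_highlight}


def main(argv):
    req_path, res_path = argv[1], argv[2]
    with open(req_path) as fh:
        req = json.load(fh)
    res = OPS[req["op"]](req)
    with open(res_path, "w") as fh:
        json.dump(res, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
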