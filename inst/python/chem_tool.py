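#!/usr/bin/env python
"""Batch chemistry worker for the molconsist R package.

Reads a TSV of requests, writes a TSV of results. All structure-level
chemistry (parsing, Standard InChI generation, FICTS standardisation
operators, corruption injection) happens here via RDKit, which embeds the
IUPAC InChI library. Field values are backslash-escaped so MOL blocks
travel as single TSV fields.

Modes:
  version                       -- toolkit/InChI version line
  pipeline --variants L1,L2,..  -- convert (mol|smiles|inchi) -> Standard
                                   InChI, then standardize under each
                                   FICTS variant label
  op --op F|I|C|T|S             -- one standardisation operator,
                                   SMILES -> canonical SMILES
  genmol                        -- SMILES -> MOL V2000 block (2D coords)
  mkrecord --library PATH       -- build one synthetic record: MOL block,
                                   per-channel identifiers with class-
                                   contract-verified corruption
"""

import argparse
import random
import sys

from rdkit import Chem
from rdkit.Chem import rdDepictor
from rdkit.Chem.MolStandardize import rdMolStandardize
from rdkit.Chem.inchi import MolToInchi, MolFromInchi
from rdkit.RDLogger import DisableLog
import rdkit

DisableLog("rdApp.*")

_UNCHARGER = rdMolStandardize.Uncharger()
_TAUT = rdMolStandardize.TautomerEnumerator()

FICTS_LETTERS = "FICTS"


# ---------------------------------------------------------------- escaping

def esc(s):
    return (s.replace("\\", "\\\\").replace("\t", "\\t")
             .replace("\r", "\\r").replace("\n", "\\n"))


def unesc(s):
    out = []
    it = iter(range(len(s)))
    i = 0
    while i < len(s):
        c = s[i]
        if c == "\\" and i + 1 < len(s):
            n = s[i + 1]
            out.append({"\\": "\\", "t": "\t", "n": "\n", "r": "\r"}.get(n, n))
            i += 2
        else:
            out.append(c)
            i += 1
    return "".join(out)


def read_rows(path):
    rows = []
    with open(path, "r", encoding="utf-8") as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            rows.append([unesc(f) for f in line.split("\t")])
    return rows


def write_rows(path, rows):
    with open(path, "w", encoding="utf-8") as fh:
        for r in rows:
            fh.write("\t".join(esc(str(f)) for f in r) + "\n")


# ---------------------------------------------------------------- convert

def _inchi_of(mol):
    try:
        s = MolToInchi(mol)
    except Exception:
        return None
    return s if s else None


def parse_channel(kind, value):
    """Return (mol, failure_class). Exactly one is not None."""
    if value is None or value == "":
        return None, "empty_structure"
    if kind == "mol":
        lines = value.split("\n")
        if len(lines) >= 4 and "V3000" in lines[3]:
            return None, "parse_error"
        try:
            mol = Chem.MolFromMolBlock(value)
        except Exception:
            mol = None
        if mol is None:
            return None, "parse_error"
    elif kind == "smiles":
        try:
            mol = Chem.MolFromSmiles(value)
        except Exception:
            mol = None
        if mol is None:
            return None, "parse_error"
    elif kind == "inchi":
        if not value.startswith("InChI="):
            return None, "parse_error"
        try:
            mol = MolFromInchi(value)
        except Exception:
            mol = None
        if mol is None:
            return None, "parse_error"
    else:
        return None, "other"
    if mol.GetNumAtoms() == 0:
        return None, "empty_structure"
    if any(a.GetAtomicNum() == 0 for a in mol.GetAtoms()):
        return None, "query_atom"
    return mol, None


def convert(kind, value):
    """(ok, inchi, failure_class)"""
    mol, fail = parse_channel(kind, value)
    if mol is None:
        return False, "", fail
    inchi = _inchi_of(mol)
    if inchi is None:
        return False, "", "other"
    return True, inchi, ""


# ------------------------------------------------------- FICTS operators

def op_fragment(mol):
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) <= 1:
        return mol
    best, best_key = None, None
    for f in frags:
        n = f.GetNumHeavyAtoms()
        ink = _inchi_of(f) or "￿"
        key = (-n, ink)  # most heavy atoms; tie -> lexicographically smaller InChI
        if best_key is None or key < best_key:
            best, best_key = f, key
    return best


def op_isotope(mol):
    m = Chem.Mol(mol)
    for a in m.GetAtoms():
        a.SetIsotope(0)
    return m


def op_charge(mol):
    try:
        return _UNCHARGER.uncharge(mol)
    except Exception:
        return mol


def op_tautomer(mol):
    """Canonical tautomer; on enumeration cap/failure return input (noted)."""
    try:
        return _TAUT.Canonicalize(mol), ""
    except Exception:
        return mol, "tautomer_cap"


def op_stereo(mol):
    m = Chem.Mol(mol)
    Chem.RemoveStereochemistry(m)
    return m


def parse_label(label):
    """FICTS variant label -> set of insensitive letters."""
    if len(label) != 5:
        raise ValueError("bad FICTS label: %r" % label)
    ins = set()
    for i, ch in enumerate(label):
        if ch == "u":
            ins.add(FICTS_LETTERS[i])
        elif ch != FICTS_LETTERS[i]:
            raise ValueError("bad FICTS label: %r" % label)
    return ins


def standardize_mol(mol, ins):
    """Apply enabled operators in fixed order F->I->C->T->S."""
    note = ""
    if "F" in ins:
        mol = op_fragment(mol)
    if mol is None or mol.GetNumAtoms() == 0:
        return None, "empty_structure", note
    if "I" in ins:
        mol = op_isotope(mol)
    if "C" in ins:
        mol = op_charge(mol)
    if "T" in ins:
        mol, note = op_tautomer(mol)
    if "S" in ins:
        mol = op_stereo(mol)
    return mol, "", note


def _standardize_once(inchi, ins):
    try:
        mol = MolFromInchi(inchi)
    except Exception:
        mol = None
    if mol is None:
        return False, "", "parse_error", ""
    mol, fail, note = standardize_mol(mol, ins)
    if fail:
        return False, "", fail, note
    out = _inchi_of(mol)
    if out is None:
        return False, "", "other", note
    return True, out, "", note


def standardize_inchi(inchi, ins):
    """(ok, std_inchi, failure_class, note). Empty ins = identity."""
    if not ins:
        return True, inchi, "", ""
    ok, out, fail, note = _standardize_once(inchi, ins)
    if not ok or "T" not in ins:
        return ok, out, fail, note
    # The canonical-tautomer step composed with InChI regeneration is not
    # always a fixed point: InChI's own mobile-H normalisation can hand a
    # different tautomer back on re-parsing. Iterate to a fixed point,
    # breaking cycles deterministically by the smallest InChI string.
    seen = [out]
    cur = out
    for _ in range(6):
        ok2, nxt, _f, _n = _standardize_once(cur, ins)
        if not ok2 or nxt == cur:
            return True, cur, "", note
        if nxt in seen:
            return True, min(seen[seen.index(nxt):]), "", note
        seen.append(nxt)
        cur = nxt
    return True, min(seen), "", note


# ----------------------------------------------------------------- modes

def mode_pipeline(args):
    variants = [v for v in (args.variants.split(",") if args.variants else []) if v]
    var_sets = [(v, parse_label(v)) for v in variants]
    rows = read_rows(args.infile)
    conv_cache = {}
    std_cache = {}
    out = []
    for r in rows:
        rid, kind, value = r[0], r[1], r[2]
        ck = (kind, value)
        if ck not in conv_cache:
            conv_cache[ck] = convert(kind, value)
        ok, inchi, fail = conv_cache[ck]
        rec = [rid, "1" if ok else "0", fail, inchi]
        for vlabel, ins in var_sets:
            if not ok:
                rec += ["0", "not_converted", "", ""]
                continue
            sk = (vlabel, inchi)
            if sk not in std_cache:
                std_cache[sk] = standardize_inchi(inchi, ins)
            sok, sinchi, sfail, note = std_cache[sk]
            rec += ["1" if sok else "0", sfail, sinchi, note]
        out.append(rec)
    write_rows(args.outfile, out)


def mode_op(args):
    ins = {args.op}
    rows = read_rows(args.infile)
    out = []
    for rid, smi in rows:
        mol, fail = parse_channel("smiles", smi)
        if mol is None:
            out.append([rid, "0", fail, ""])
            continue
        mol, sfail, _ = standardize_mol(mol, ins)
        if sfail:
            out.append([rid, "0", sfail, ""])
            continue
        out.append([rid, "1", "", Chem.MolToSmiles(mol)])
    write_rows(args.outfile, out)


def to_molblock(mol):
    m = Chem.Mol(mol)
    rdDepictor.Compute2DCoords(m)
    try:
        mb = Chem.MolToMolBlock(m)
    except Exception:
        mb = Chem.MolToMolBlock(m, kekulize=False)
    return mb.rstrip("\n")


def mode_genmol(args):
    rows = read_rows(args.infile)
    out = []
    for rid, smi in rows:
        try:
            mol = Chem.MolFromSmiles(smi)
        except Exception:
            mol = None
        if mol is None:
            out.append([rid, "0", "parse_error", ""])
        else:
            out.append([rid, "1", "", to_molblock(mol)])
    write_rows(args.outfile, out)


# --------------------------------------------------------- synthetic data

CLASSES = ("clean", "stereo", "tautomer", "fragment_salt", "charge",
           "isotope", "wrong_compound", "unconvertible")

_RULES = ("F", "I", "C", "T", "S")
_OWN_RULE = {"stereo": "S", "tautomer": "T", "fragment_salt": "F",
             "charge": "C", "isotope": "I"}


class Library(object):
    def __init__(self, path):
        self.names, self.mols, self.inchis = [], [], []
        with open(path) as fh:
            header = fh.readline()
            for line in fh:
                name, smi = line.rstrip("\n").split("\t")[:2]
                m = Chem.MolFromSmiles(smi)
                self.names.append(name)
                self.mols.append(m)
                self.inchis.append(_inchi_of(m))
        self._rule_std = {}   # (idx, rule) -> std inchi
        self._allu = {}       # idx -> all-insensitive inchi

    def rule_std(self, idx, rule):
        key = (idx, rule)
        if key not in self._rule_std:
            mol, fail, _ = standardize_mol(Chem.Mol(self.mols[idx]), {rule})
            self._rule_std[key] = _inchi_of(mol) if not fail else None
        return self._rule_std[key]

    def allu(self, idx):
        if idx not in self._allu:
            mol, fail, _ = standardize_mol(Chem.Mol(self.mols[idx]), set(_RULES))
            self._allu[idx] = _inchi_of(mol) if not fail else None
        return self._allu[idx]


def _rule_std_of(mol, rule):
    m2, fail, _ = standardize_mol(Chem.Mol(mol), {rule})
    return _inchi_of(m2) if not fail else None


def _contract_ok(lib, idx, corrupt_mol, own):
    """Corruption contract: baseline InChI differs; exactly the class's own
    u-rule (and no other single u-rule) restores equality."""
    ci = _inchi_of(corrupt_mol)
    if ci is None or ci == lib.inchis[idx]:
        return False
    for rule in _RULES:
        healed = (_rule_std_of(corrupt_mol, rule) == lib.rule_std(idx, rule))
        if rule == own and not healed:
            return False
        if rule != own and healed:
            return False
    return True


def _flip_candidates(mol):
    return [a.GetIdx() for a in mol.GetAtoms() if a.GetChiralTag() in
            (Chem.ChiralType.CHI_TETRAHEDRAL_CW,
             Chem.ChiralType.CHI_TETRAHEDRAL_CCW)]


def inject_stereo(lib, idx, rng):
    cand = _flip_candidates(lib.mols[idx])
    rng.shuffle(cand)
    for ai in cand:
        m = Chem.Mol(lib.mols[idx])
        a = m.GetAtomWithIdx(ai)
        a.SetChiralTag(Chem.ChiralType.CHI_TETRAHEDRAL_CW
                       if a.GetChiralTag() == Chem.ChiralType.CHI_TETRAHEDRAL_CCW
                       else Chem.ChiralType.CHI_TETRAHEDRAL_CCW)
        if _contract_ok(lib, idx, m, "S"):
            return m
    return None


def inject_tautomer(lib, idx, rng):
    try:
        cands = list(_TAUT.Enumerate(lib.mols[idx]))
    except Exception:
        return None
    rng.shuffle(cands)
    for m in cands:
        if _contract_ok(lib, idx, m, "T"):
            return m
    return None


def inject_fragment_salt(lib, idx, rng):
    salt = rng.choice(["Cl", "O"])  # hydrochloride or hydrate companion
    m = Chem.CombineMols(lib.mols[idx], Chem.MolFromSmiles(salt))
    if _contract_ok(lib, idx, m, "F"):
        return m
    return None


_ACID_O = Chem.MolFromSmarts("[OX2H1][CX3]=O")
_SULF_O = Chem.MolFromSmarts("[OX2H1][SX4](=O)=O")
_BASIC_N = Chem.MolFromSmarts("[NX3;H2,H1;!$(NC=O);!$(NC=S);!$(N~[!#6;!#1])]")


def inject_charge(lib, idx, rng):
    mol = lib.mols[idx]
    edits = []
    for patt in (_ACID_O, _SULF_O):
        for match in mol.GetSubstructMatches(patt):
            edits.append(("deprot", match[0]))
    for match in mol.GetSubstructMatches(_BASIC_N):
        edits.append(("prot", match[0]))
    rng.shuffle(edits)
    for kind, ai in edits:
        m = Chem.Mol(mol)
        a = m.GetAtomWithIdx(ai)
        try:
            if kind == "deprot":
                if a.GetTotalNumHs() < 1:
                    continue
                a.SetFormalCharge(-1)
                a.SetNumExplicitHs(a.GetTotalNumHs() - 1)
                a.SetNoImplicit(True)
            else:
                a.SetFormalCharge(1)
                a.SetNumExplicitHs(a.GetTotalNumHs() + 1)
                a.SetNoImplicit(True)
            Chem.SanitizeMol(m)
        except Exception:
            continue
        if _contract_ok(lib, idx, m, "C"):
            return m
    return None


def inject_isotope(lib, idx, rng):
    pt = Chem.GetPeriodicTable()
    order = list(range(lib.mols[idx].GetNumAtoms()))
    rng.shuffle(order)
    for ai in order:
        m = Chem.Mol(lib.mols[idx])
        a = m.GetAtomWithIdx(ai)
        if a.GetAtomicNum() == 0:
            continue
        a.SetIsotope(int(round(pt.GetMostCommonIsotopeMass(a.GetAtomicNum()))) + 1)
        if _contract_ok(lib, idx, m, "I"):
            return m
    return None


def inject_wrong_compound(lib, idx, rng):
    order = list(range(len(lib.mols)))
    rng.shuffle(order)
    for j in order:
        if j == idx:
            continue
        if lib.allu(j) is not None and lib.allu(j) != lib.allu(idx):
            return Chem.Mol(lib.mols[j])
    return None


_INJECTORS = {"stereo": inject_stereo, "tautomer": inject_tautomer,
              "fragment_salt": inject_fragment_salt, "charge": inject_charge,
              "isotope": inject_isotope, "wrong_compound": inject_wrong_compound}

BAD_SMILES = "C1CC("        # unclosed ring + branch: fails to parse
BAD_INCHI = "InChI=1S/C2H6Oq/cxx"


def channel_values(lib, idx, cls, channel, rng):
    """Return the (smiles-ish) identifier value for one channel, or None if
    the class contract is unachievable on this base molecule.
    For channel 'iupac' the value is the SMILES the fixture name resolves to."""
    if cls == "clean":
        mol = lib.mols[idx]
    elif cls == "unconvertible":
        return BAD_INCHI if channel == "inchi" else BAD_SMILES
    else:
        mol = _INJECTORS[cls](lib, idx, rng)
        if mol is None:
            return None
    if channel == "inchi":
        return _inchi_of(mol)
    return Chem.MolToSmiles(mol)


def mode_mkrecord(args):
    lib = Library(args.library)
    rows = read_rows(args.infile)
    out = []
    for rid, base_idx, cs, ci, cn, seed in rows:
        rng = random.Random(int(seed))
        idx = int(base_idx)
        done = False
        for attempt in range(80):
            vals = {}
            feasible = True
            for channel, cls in (("smiles", cs), ("inchi", ci), ("iupac", cn)):
                if cls == "none":
                    vals[channel] = ""
                    continue
                v = channel_values(lib, idx, cls, channel, rng)
                if v is None:
                    feasible = False
                    break
                vals[channel] = v
            if feasible:
                done = True
                break
            idx = rng.randrange(len(lib.mols))
        if not done:
            out.append([rid, "0", str(idx), "", "", "", "", "", ""])
            continue
        mb = to_molblock(lib.mols[idx])
        out.append([rid, "1", str(idx), mb, lib.inchis[idx], lib.allu(idx) or "",
                    vals["smiles"], vals["inchi"], vals["iupac"]])
    write_rows(args.outfile, out)


def mode_version(args):
    with open(args.outfile, "w") as fh:
        fh.write("rdkit\t%s\n" % rdkit.__version__)


def main(argv=None):
    p = argparse.ArgumentParser()
    p.add_argument("mode", choices=["pipeline", "op", "genmol", "mkrecord",
                                    "version"])
    p.add_argument("--in", dest="infile")
    p.add_argument("--out", dest="outfile", required=True)
    p.add_argument("--variants", default="")
    p.add_argument("--op", dest="op", choices=list(_RULES))
    p.add_argument("--library")
    args = p.parse_args(argv)
    {"pipeline": mode_pipeline, "op": mode_op, "genmol": mode_genmol,
     "mkrecord": mode_mkrecord, "version": mode_version}[args.mode](args)
    return 0


if __name__ == "__main__":
    sys.exit(main())
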