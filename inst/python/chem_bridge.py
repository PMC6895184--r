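"""Batched RDKit helper for the uvvisdb R package.

Reads one JSON request object from stdin and writes one JSON response to
stdout.  Kept to a single process invocation per batch so that R callers pay
the interpreter start-up cost once per vector, not once per molecule.

Request:  {"op": <str>, "smiles": [<str>, ...], ...op-specific keys}
Response: {"ok": true, "result": [...]}  or  {"ok": false, "error": <str>}

Ops:
  canonical   -> canonical SMILES per input (null where unparseable)
  inchikey    -> standard InChIKey per input (null where unparseable)
  randomize   -> n randomized SMILES spellings per input (seeded)
  electrons   -> total electron count per input, explicit H included
                 (independent oracle for the R-side electron_count)
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem.inchi import MolToInchiKey

RDLogger.DisableLog("rdApp.*")


def _mol(smi):
    if smi is None:
        return None
    return Chem.MolFromSmiles(smi)


def op_canonical(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        out.append(Chem.MolToSmiles(m) if m is not None else None)
    return out


def op_inchikey(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        try:
            out.append(MolToInchiKey(m))
        except Exception:
            out.append(None)
    return out


def op_randomize(req):
    n = int(req.get("n", 1))
    seed = int(req.get("seed", 1))
    out = []
    for i, smi in enumerate(req["smiles"]):
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        spellings = []
        for j in range(n):
            # doRandom randomizes the atom output order deterministically
            # under the global RNG seeded per (input, replicate)
            import random

            random.seed(seed + 7919 * i + j)
            idx = list(range(m.GetNumAtoms()))
            random.shuffle(idx)
            rm = Chem.RenumberAtoms(m, idx)
            spellings.append(Chem.MolToSmiles(rm, canonical=False))
        out.append(spellings)
    return out


def op_electrons(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        mh = Chem.AddHs(m)
        out.append(sum(a.GetAtomicNum() for a in mh.GetAtoms()))
    return out


OPS = {
    "canonical": op_canonical,
    "inchikey": op_inchikey,
    "randomize": op_randomize,
    "electrons": op_electrons,
}


def main():
    try:
        req = json.load(sys.stdin)
        fn = OPS[req["op"]]
        res = {"ok": True, "result": fn(req)}
    except Exception as exc:  # surfaced to R as a classed error
        res = {"ok": False, "error": "%s: %s" % (type(exc).__name__, exc)}
    json.dump(res, sys.stdout)


if __name__ == "__main__":
    main()
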