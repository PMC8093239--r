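"""Independent XMLBIF posterior oracle.

Parses an XMLBIF 0.3 document with lxml and computes exact posterior
marginals of one target node by brute-force enumeration of the full joint
table. Used by the test suite as a cross-check of the R engine; shares no
code with it.

Usage: python xmlbif_posterior.py NETWORK.xml TARGET [NODE=STATE ...]
Prints one "state probability" pair per line, in outcome order.

Table convention: parent configurations enumerated with the first GIVEN
slowest and the last GIVEN fastest; outcomes contiguous per configuration.
"""
import sys
from itertools import product

from lxml import etree


def parse(path):
    tree = etree.parse(path)
    states = {}
    for var in tree.iter("VARIABLE"):
        name = var.findtext("NAME")
        states[name] = [o.text for o in var.findall("OUTCOME")]
    cpts = {}
    parents = {}
    for d in tree.iter("DEFINITION"):
        node = d.findtext("FOR")
        given = [g.text for g in d.findall("GIVEN")]
        table = [float(x) for x in d.findtext("TABLE").split()]
        k = len(states[node])
        rows = {}
        cfgs = list(product(*[states[p] for p in given])) if given else [()]
        assert len(table) == k * len(cfgs), node
        for i, cfg in enumerate(cfgs):
            rows[cfg] = table[i * k:(i + 1) * k]
        parents[node] = given
        cpts[node] = rows
    return states, parents, cpts


def posterior(states, parents, cpts, target, evidence):
    names = list(states)
    num = [0.0] * len(states[target])
    den = 0.0
    for combo in product(*[states[v] for v in names]):
        assign = dict(zip(names, combo))
        if any(assign[v] != s for v, s in evidence.items()):
            continue
        p = 1.0
        for v in names:
            cfg = tuple(assign[q] for q in parents[v])
            p *= cpts[v][cfg][states[v].index(assign[v])]
        den += p
        num[states[target].index(assign[target])] += p
    return [x / den for x in num]


def main(argv):
    path, target = argv[1], argv[2]
    evidence = dict(a.split("=", 1) for a in argv[3:])
    states, parents, cpts = parse(path)
    for s, p in zip(states[target],
                    posterior(states, parents, cpts, target, evidence)):
        print(s, repr(p))


if __name__ == "__main__":
    main(sys.argv)
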