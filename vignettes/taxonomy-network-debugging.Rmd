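---
title: "Debugging is-a structure and mappings in networked taxonomies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Debugging is-a structure and mappings in networked taxonomies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxodebug)
```

## The problem

Biomedical taxonomies — ontologies restricted to named concepts and
subsumption (is-a) axioms — are routinely connected into networks by
alignments: sets of mappings asserting that a concept of one ontology is
equivalent to (`≡`), subsumed by (`→`) or subsumes (`←`) a concept of
another. Both the is-a structure and the mappings contain defects: relations
that should be asserted but are not (missing), and asserted or derivable
relations that do not hold in the domain (wrong). A common source of wrong
is-a relations is the confusion of is-a with part-of (an ascending colon is
*part of* a colon, not a *kind of* colon).

`taxodebug` implements a unified, logic-based debugging workflow that needs
no external knowledge source: the network itself is the domain knowledge.
The induced ontology of a network is the single taxonomy whose concepts are
the union of all member concepts and whose asserted axioms are the union of
all intra-ontology axioms with the directed axioms representing the
mappings (each equivalence expanded into its two directed components, each
independently removable).

## The workflow and its model

All reasoning is reflexive-transitive reachability over atomic subsumption
axioms, organised in *scoped knowledge bases*: one per ontology, one per
aligned ontology pair (the two ontologies plus their alignment), and one for
the whole network. Cycles are permitted — equivalences create two-cycles by
construction — and derivability is simply directed reachability.

**Phase 1 — detection.** A *candidate missing is-a relation* (CMI) of
ontology `O` is an ordered pair `(a, b)` of concepts of `O` such that
`a is-a b` is derivable from the network knowledge base but not from `O`'s
own; a *candidate missing mapping* (CMM) is the analogue for a pair of
ontologies and their alignment. Detection is restricted to pairs of *mapped
concepts* (endpoints of at least one live mapping): when the asserted
structure and mappings are correct, repairing the candidates between mapped
concepts repairs every derivable-but-locally-underivable pair — a property
the test suite verifies empirically by an all-pairs residual scan over 100
seeded synthetic networks. Redundant candidates — those entailed by the
repair of a retained, more informative candidate (`(c, d)` is at least as
informative as `(a, b)` when `a is-a c` and `d is-a b` hold locally) — are
filtered out, with lexicographic tie-breaks inside mutually informative
groups. For validation the remaining candidates are grouped into connected
components of the comparability relation in the network knowledge base.

**Phase 2 — validation.** A domain expert (or a scripted policy) partitions
candidates into missing and wrong relations. Each batch is checked for
contradictions before anything commits: no pair may receive both decisions
across the whole session, and no wrong-validated pair may be derivable from
the missing-validated pairs plus executed additions alone. Both rules are
sound — a verdict set violating either cannot be realised by any repaired
network — and a rejected batch leaves the session untouched. The precise
contradiction test used interactively by the original system is
unpublished; these two rules are this package's contract. Recommendations
(never auto-decisions) come from part-of knowledge in the host ontology and
from a pluggable, deterministic knowledge oracle queried with normalised
labels (lowercase, underscores to spaces); the shipped oracles are a
dictionary-backed table and a file-backed table.

**Phase 3 — repair.** Every validated missing relation is immediately
asserted *provisionally* in its scope knowledge bases: this is its least
informative repair, pending a possibly better one, and it is validated
knowledge the rest of the repairing may use.

*Wrong relations* are repaired by removal. All minimal justifications of
the defect pair — edge sets of simple directed paths, filtered to
subset-minimal sets — are enumerated in the current network knowledge base;
the user removes at least one axiom from every justification. Provisional
axioms and added repairing actions are never removable. The recommendation
scores every removable axiom by how often it occurs in the minimal hitting
sets of the per-defect justification families, then by how many defects it
touches, then by whether it was chosen before; an axiom that repairs
several wrong relations at once therefore outranks axioms that repair only
one. Hitting sets are computed per defect for scoring (the joint
minimal-hitting-set operation over several defects is also exposed);
computing them jointly would let a single defect with many hitting sets
dominate the count and invert the intended preference. Executions are
transactional: after removing the chosen axioms, the defect pairs *and*
every removed axiom's own pair must be underivable from the network,
otherwise the call is rejected and the session is bit-identical.

*Missing relations* are repaired by addition. For defect `(a, b)` in scope
knowledge base `KB`, `Source(a,b)` is the reflexive super-concept cone of
`a` minus that of `b`, `Target(a,b)` the reflexive sub-concept cone of `b`
minus that of `a`, and the repair space is `Source × Target` minus
conflicts with known wrong relations: pairs that are themselves registered
wrong or removed, and pairs at least as informative as such a pair over
validated-correct axioms. By this set-difference construction every
repairing action contributes (adding it derives the defect pair), is a
single axiom, and introduces no non-validated equivalence. One deliberate
deviation from the pure product construction: the defect pair itself is
always offered (subject only to the conflict filters). When two unrepaired
missing relations provisionally assert opposite directions — as happens
when both components of a displaced equivalence are validated missing —
the cone differences empty out and the product alone would leave both
defects permanently unrepairable; offering the promotion of the provisional
axiom resolves the deadlock and matches the intended "least informative
member" reading. Recommendations return the informativeness-maximal
repair-space elements supported by the oracle, falling back (flagged) to
the maximal elements when nothing is supported.

**Consequence propagation.** After every executed repair, all knowledge
bases are rebuilt from scratch and the registers reconciled: wrong defects
whose pair became underivable are repaired; missing defects derivable
without any provisional axiom are repaired by others; previously repaired
defects that regressed are reinstated; detection re-runs on every scope and
registers fresh candidates. Recompute-from-scratch (rather than
incremental closure maintenance) is sufficient at the intended scale and
immune to stale state; a content-keyed memo transparently shares identical
knowledge bases within one state. The session is *done* when no candidates
or unrepaired defects remain and the four structural-repair requirements
hold: validated missing is-a relations derivable from their repaired host
ontologies (without provisionals), missing mappings from their repaired
pairs, and validated wrong is-a relations and mappings underivable from the
repaired network.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `max_paths` | 1000 | simple paths enumerated per justification query |
| `max_len` | 20 | maximum axioms per derivation path |
| `max_hs_size` | 5 | largest minimal hitting set enumerated |
| `max_hs_count` | 10000 | maximum number of minimal hitting sets |
| `max_iterations` | 50 | scripted-session iteration cap |

Justification and hitting-set enumeration are exponential in the worst
case; the caps keep queries bounded and every truncation is surfaced via a
`truncated` flag so callers can distinguish "all" from "first k".
Deterministic iteration order (concepts and axioms sorted by identifier,
sizes before lexicographic tie-breaks) makes every operation reproducible.

## The synthetic generator and what passing tests show

`synthesize_network()` emulates the study setting: a random true
subsumption DAG over a global concept universe; each of `n_ontologies`
taxonomies holds a pool of concepts shared by all (fraction
`overlap_fraction`, spread through the topological order) plus a private
block, and asserts the transitive reduction of the closure of the true
*direct* edges among its own concepts — so knowledge carried by concepts an
ontology lacks stays derivable only via the network, which is exactly the
situation intrinsic detection exists for. Shared concepts are linked by
equivalence mappings in every pairwise alignment. Defects are then planted:
true axioms hidden with probability `p_omit` (planted missing is-a
relations), false axioms added at rate `p_spurious` (planted wrong is-a
relations), and mappings rewired to non-corresponding concepts with
probability `p_wrong_mapping` (planted wrong mappings).

Defaults — 3 ontologies × 60 concepts, edge density 0.04, overlap 0.4,
`p_omit` 0.1, `p_spurious` 0.03, `p_wrong_mapping` 0.02 — keep networks
small enough for the brute-force oracles while exercising every code path.
Corruption is restricted to concepts shared with other ontologies (and, for
spurious edges and rewired mappings, shared with a third ontology): a
defect whose evidence is absent from the rest of the network is invisible
to *any* method that uses only network-intrinsic knowledge, so unrestricted
planting would make 100% recovery unattainable by construction rather than
by implementation defect. That is also the honest limitation of what the
recovery tests show: they certify the workflow on defects that are
recoverable from the network, and say nothing about defects only external
knowledge could reveal. The generator likewise makes no claim to the
statistical shape of real biomedical ontologies (branching factors, depth,
synonymy); it exists to exercise the logic with known ground truth.

The ground-truth policy stands in for the domain expert: candidates are
validated missing exactly when true-reachable; wrong defects are repaired
by removing the corrupted axioms found on derivation paths (expanded to a
fixpoint so removed axioms' own pairs become underivable too — sound
because every derivation path of a non-true pair must contain a corrupted
axiom); missing defects are repaired with the informativeness-maximal
truth-consistent action, falling back to the defect pair itself.

## Worked fragments

`paper_fixture()` reconstructs four published anatomy fragments with
machine-checkable expected facts: the ascending-colon/colon fragment (one
wrong candidate whose justification holds two equivalence components and
one asserted axiom), the grey/white-matter fragment (three wrong
candidates, unique three-axiom justifications, the reverse equivalence
component shared by two and therefore top removal priority), the
laryngeal-cartilage fragment (the informative action repairs three other
missing relations as a side effect), and the viscerocranium-bone fragment
(the informative action repairs the maxilla and lacrimal defects). The
white-matter fragment's unprinted connecting edges are reconstructed
minimally so that exactly the three published candidates appear; the
reconstruction is tested against the published behaviours only.

## Numerical and design choices

- Concept identity is the identifier; labels are display-only and used,
  normalised, solely in oracle lookups.
- `(a, b)` and `(b, a)` are distinct candidates (an equivalence shows up as
  two directed candidates).
- Redundancy filtering evaluates informativeness against the scope-local
  knowledge base including provisional axioms at detection time.
- Self-axioms are rejected; duplicate axiom definitions collapse to one.
- Justification paths are simple (no repeated concept); subset-minimality
  is filtered after enumeration.
- Degenerate inputs: empty ontologies, networks without alignments,
  isolated concepts, and empty validated sets all yield well-defined empty
  results rather than errors.
- Test problem sizes: the oracle-equivalence suites run on graphs of up to
  200 concepts (100 seeds) and instances of up to 12 axioms for exhaustive
  enumeration; the recovery and completeness suites run 100 scripted
  sessions each at the generator defaults; property suites use 20–30
  concept networks.

## Limitations

Only named-concept subsumption participates in reasoning: no role
restrictions, disjointness, or annotations beyond labels, and part-of pairs
inform recommendations only. Live lexical resources are out of scope by
design — the oracle interface is deterministic and file- or table-backed.
OWL input must be converted externally; the readers cover a plain TSV
dialect and the OBO 1.2 subset (`id`, `name`, `is_a`,
`relationship: part_of`, `is_obsolete`). Repair never strengthens a
subsumption mapping into an equivalence on its own: only directed axioms
are ever added.

## A complete example

```{r example}
fx <- paper_fixture("colon")
session <- repair_session(fx$network)
cands <- detect_candidates(session, "ncia")
cands

# validate the candidate as wrong (it is a part-of, not an is-a)
session$CMI <- cands
session <- record_verdicts(session, list(list(
  kind = "CMI", scope = cands$scope, sub = cands$sub, sup = cands$sup,
  decision = "wrong")))

# one justification, three removable axioms
removal_candidates(session, session$WI)$eligible

# remove the asserted is-a axiom and check the requirements
session <- execute_removals(session, session$WI,
                            "ama:ascending colon->ama:colon")
network_status(session)
```
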