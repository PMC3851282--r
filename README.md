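# taxodebug

Detecting and repairing defects in the is-a structure of taxonomies
connected into a network by alignments.

Biomedical ontologies are often used together, linked by alignments —
sets of mappings stating that a concept of one ontology is equivalent to
(`≡`), subsumed by (`→`) or subsumes (`←`) a concept of another. Both the
is-a (subsumption) structure and the mappings contain defects: missing
relations, and wrong ones (frequently an is-a/part-of confusion). This
package implements a unified, logic-based debugging workflow for ontology
engineers and curators of such networks. It needs no external knowledge
source: the *induced ontology* of the network — the union of all concepts,
intra-ontology is-a axioms and mapping-derived axioms — is itself the
domain knowledge used to find defects.

The core notions:

- **Candidate missing is-a relation (CMI)** of ontology *O*: a pair
  *(a, b)* of mapped concepts of *O* with *a ⊑ b* derivable from the
  network knowledge base *KB_N* but not from *KB_O*. A **candidate
  missing mapping (CMM)** is the analogue for an ontology pair and its
  alignment. Candidates are validated by an expert into **missing** and
  **wrong** relations.
- **Justification**: a subset-minimal axiom set entailing a derived
  relation (the edge set of a simple subsumption path). A wrong relation
  is repaired by removing at least one axiom of every justification; a
  **minimal hitting set** of the justifications is a minimal such removal,
  and removal recommendations are ranked by hitting-set membership across
  the defects under repair.
- **Repair space** of a missing relation *(a, b)* in knowledge base *KB*:
  `Source(a,b) = super(a) − super(b)`, `Target(a,b) = sub(b) − sub(a)`,
  repairing actions `Source × Target` minus conflicts with known wrong
  relations. *(s, t)* is **more informative** than *(a, b)* when *a ⊑ s*
  and *t ⊑ b* already hold, so adding *(s, t)* also repairs *(a, b)*;
  recommendations prefer informative actions supported by a pluggable
  knowledge oracle.
- After every executed repair all **consequences** are computed: defects
  repaired by side effect, regressed repairs, and fresh candidates.

The package ships readers/writers for a plain TSV taxonomy dialect, the
OBO 1.2 subset and alignment/verdict TSV files; JSON session state; a
seeded synthetic-network generator with planted defects and ground truth;
a scripted session driver; and a command-line interface
(`inst/cli/taxodebug.R`).

## A worked example

The ascending-colon fragment: mouse anatomy asserts *ascending colon is-a
colon* (in reality a part-of relation), the second ontology maps both
concepts by equivalences.

```r
library(taxodebug)
fx <- paper_fixture("colon")
session <- repair_session(fx$network)

detect_candidates(session, "ncia")
#>   scope                  sub        sup      status
#> 1  ncia ncia:Ascending_Colon ncia:Colon unvalidated
```

One candidate: *Ascending_Colon ⊑ Colon* is derivable through the network
(via the two equivalences and the asserted axiom in the first ontology)
but not in the second ontology alone. The fixture's part-of knowledge
recommends validating it wrong; after recording that verdict, its single
justification offers three removable axioms:

```r
session$CMI <- detect_candidates(session, "ncia")
session <- record_verdicts(session, list(list(
  kind = "CMI", scope = "ncia", sub = "ncia:Ascending_Colon",
  sup = "ncia:Colon", decision = "wrong")))
removal_candidates(session, session$WI)$eligible
#> [[1]]
#> [1] "ama:ascending colon->ama:colon"
#> [2] "ama:colon->ncia:Colon"
#> [3] "ncia:Ascending_Colon->ama:ascending colon"

session <- execute_removals(session, session$WI,
                            "ama:ascending colon->ama:colon")
network_status(session)
#> Network status: done
#>   open candidates: 0; unrepaired defects: 0
```

Removing the asserted is-a axiom repairs the wrong relation; the session
is done — no candidates remain and all four structural-repair
requirements hold. `export_repaired(session, dir)` then writes the
repaired ontologies, alignment and a change report.

For non-interactive use, `run_scripted_session(network, policy)` loops
detection, validation and repair under a decision policy;
`synthesize_network(synthetic_spec(seed = 1))` generates a seeded network
with planted defects whose ground truth drives `truth_policy()`. See the
vignette (`vignettes/taxonomy-network-debugging.Rmd`) for the full model
and design choices.

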