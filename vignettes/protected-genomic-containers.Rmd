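---
title: "Protected genomic containers: model, rules and cryptographic choices"
author: "GenomicVault"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protected genomic containers: model, rules and cryptographic choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GenomicVault)
```

# The problem and the model

Genomic archives need protection that is both *granular* (encrypt one
sample's reads, sign one study's metadata) and *governable* (state in a
machine-evaluable form who may do what, under which conditions). This
package models both concerns around a hierarchical container in the style
of the MPEG-G transport format, working in Access Unit Container (AUC)
organization: a File holds Dataset Groups (a group corresponds to an EGA
Study or NCBI BioProject), each group holds Datasets (an EGA dataset or
NCBI BioSample), datasets hold Access Units — independently accessible
chunks of coded genomic information — and access units hold Blocks of
opaque payload bytes. Descriptor-stream organization (DSC) is out of
scope: payloads here are opaque, and no coding or compression semantics
are modeled.

Because real container files can reach hundreds of gigabytes, the working
representation is the *file system itself*: every box is a directory
(`dg_X`, `dt_X`, `au_X`), every information element a small file (`flhd`,
`dghd`, `dgmd`, `dgpr`, `dthd`, `dtmd`, `dtpr`, `labl`, `dtin`, `auhd`,
`auin`, `aupr`, `block_X`). Each operation edits one file in place, and the
single-file form is produced only on demand.

## The packed box stream

`packContainer()` emits an ISO-BMFF-like stream: every box is a 4-byte
ASCII type code, an 8-byte big-endian payload length, and the payload;
container boxes (`flcn`, `dgcn`, `dtcn`, `aucn`) nest their children's
boxes, and leaf boxes reuse the file names above. The stream opens with
the 8-byte magic tag `GIPAMS01` followed by a single `flcn` box, so a
packed file is recognizable from its first bytes; the tag is deliberately
not the real MPEG-G brand, as the format here is a functional dialect,
not a claim of standard conformance. Children are always emitted in
ascending id order, which makes packing a pure function of the tree:
equal trees give byte-identical streams, and `unpackContainer()` followed
by `packContainer()` reproduces the input exactly. Access-unit protection
(`aupr`) and the dataset block index (`dtin`) extend the two-letter naming
pattern to levels where only the pattern, not the name, is prescribed.
All genomic coordinates carried in rules and indices are 1-based inclusive.

# Privacy rules

Rules are expressed in a subset of XACML 3.0: a `Policy` with a
rule-combining algorithm holds `Rule`s, each with a target (required
subject *role* in the XACML 1.0 access-subject category, and *action*,
an API method name such as `GetDataBySimpleFilter`) and a conjunction of
conditions over request attributes. Four condition operators cover the
genomic vocabulary: string/integer equality, boolean equality, an integer
cap (`read_count` at most a limit — a cap rather than an exact match,
since a maximum is the operationally meaningful reading of a read-count
constraint), and region containment: the request's
`[start_position, end_position]` must lie inside the rule's inclusive
interval, the conservative reading for rules that protect regions. The
protected resource is never named in a rule; a rule governs the dataset
group or dataset whose protection box contains it.

Decision semantics follow XACML conventions: a target mismatch (or a
missing target attribute) makes the rule `NotApplicable`; with a matching
target, any false condition gives `NotApplicable`, a missing or ill-typed
condition attribute (with no false condition) gives `Indeterminate`, and
otherwise the rule's effect applies. At policy level, `deny-overrides`
(the default) ranks Deny > Indeterminate > Permit; `permit-overrides`
mirrors it; `first-applicable` takes the first non-NotApplicable rule.
A policy where nothing applies returns `NotApplicable` rather than Deny
— the choice between the two is not forced by the model, and keeping
them distinct lets the hierarchy decide; every caller in the package
treats any non-Permit as *not granted*. Whether a failed condition should
be `NotApplicable` or `Deny` is likewise an open design point; the package
follows the XACML convention (`NotApplicable`).

Only single-valued requests are accepted (one value per attribute id):
multi-valued attribute bags are a XACML feature with subtle matching
semantics that nothing in this domain requires, so they are rejected
loudly rather than half-supported. Out-of-subset policy documents
(PolicySet, Obligations, advice, unknown functions) raise an
`xacml_unsupported_feature` error naming the offending element, rather
than being silently ignored. The region-containment condition serializes
under a package-specific `FunctionId` URN because standard XACML has no
two-designator interval-containment function; everything else uses
standard function and category URNs.

`buildWorkedExample()` returns the package's reference rule — practitioner
/ GetDataBySimpleFilter / Emergency / read count ≤ 5000 / no multiple
alignments / reference 4 / region within 40,810,027..41,216,714 inclusive
— together with a non-matching request whose role differs and which
carries a date attribute no condition examines (attributes without a
matching condition are simply carried, never matched). The acceptance
script recovers all four numeric constants of this rule purely by probing
the decision boundary, which exercises target matching, every condition
operator, XML round-tripping and the hierarchical authorizer in one sweep.

# Hierarchical authorization

Two algorithms connect the rule levels, balancing a group-wide default
against dataset specificity:

* **Dataset request** (`authorizeDataset`): dataset rules are checked
  first; a Permit is final — the group-wide policy must not hide
  specificities of the dataset, so a dataset-level Permit survives even an
  explicit group-level Deny. If the dataset does not grant (Deny,
  NotApplicable, or no policy file at all), the *same* request is
  evaluated against the group; a group Permit is delegated downward and
  recorded by appending the boolean provenance attribute
  `granted_by_dataset_group` to the request (the concept exists in the
  model; the attribute id is this package's choice). Delegation is final:
  the annotated request is not re-evaluated against dataset rules — the
  alternative (re-evaluation, enabling rules that match on the provenance
  attribute) is noted as a possible extension.
* **Group request** (`authorizeDatasetGroup`): anything but a group-level
  Permit denies outright. When the group grants, each dataset is reviewed
  going down the hierarchy; a dataset with *no policy file* inherits the
  grant, while a dataset whose policy exists but yields Deny *or*
  NotApplicable is blocked — an existing policy that does not grant is a
  diverging access rule, not an inheritance case. Granted and blocked
  sets are disjoint and cover the group.

`authorizeOperation()` is the operation-level gate: it injects the
`action-id` attribute, checks ownership for mutating operations (the file
header may carry an owner, matched against the request's `subject-id`
before any policy evaluation), dispatches to the level-appropriate
algorithm, and appends exactly one JSON-lines audit record per call
(timestamp, subject, operation, target, outcome) when an audit log is
configured — denied operations are precisely the events such a log exists
to capture. Only container creation is exempt from authorization: there
is nothing to protect yet. With no governing policy, read operations are
denied (a closed-by-default archive) while mutating operations fall back
to the ownership check, so a freshly created container remains editable
by its owner before any policy is attached. Rules exist only at group and
dataset level; access units carry protection (encryption, signatures) but
no rules, as no API action addresses them individually.

# Cryptographic design

All primitives come from the system OpenSSL library via the `openssl`
package; the package composes them but implements no primitive itself.

* **Authenticated encryption.** Payloads are sealed with an
  encrypt-then-MAC construction: AES-256-CTR under an encryption subkey,
  then HMAC-SHA256 (truncated to 16 bytes) over nonce, associated data
  and ciphertext under a distinct MAC subkey; both subkeys are derived
  from the 32-byte content key by domain-separated SHA-256. This
  construction was chosen over an integrated AEAD mode because the
  R-level bindings available expose GCM only without its authentication
  tag, and an unauthenticated mode is not acceptable here; encrypt-then-MAC
  with independent keys is the standard generic composition with a
  security proof. Any tag mismatch — wrong key, wrong nonce, flipped
  ciphertext bit, ciphertext moved to a different target — raises an
  `integrity_error`; garbage plaintext is never returned. The target
  selector string is bound as associated data, so ciphertexts cannot be
  transplanted between targets.
* **Selective protection.** `encryptTarget()` replaces exactly one payload
  (a block or a metadata file) with its ciphertext and records the entry
  — algorithm id, nonce, key reference — in the nearest enclosing
  protection box (block → the access unit's `aupr`, `dtmd` → `dtpr`,
  `dgmd` → `dgpr`). No byte outside the target and its box changes, so
  any mix of protected and plaintext elements is expressible: encrypted
  metadata over plaintext reads, one encrypted block among plaintext
  siblings, signatures on metadata with encryption on data.
* **Signatures** are detached Ed25519 over the plaintext payload
  (sign-then-encrypt, so integrity remains checkable after decryption);
  signing an already-encrypted target is refused.
* **Key wrapping** derives a wrapping key from a passphrase with
  `bcrypt_pbkdf` (16 rounds) over a fresh 16-byte salt and seals the
  content key with the same AEAD; a wrong passphrase fails loudly.
  bcrypt_pbkdf is the memory-hard KDF the crypto library exposes; the
  method id is recorded in the XML so alternative KDFs can be added.
* **Envelope encryption.** The Crypt4GH-style codec wraps a fresh random
  session key once per recipient in a header packet keyed by X25519
  agreement between writer and recipient (packet key =
  SHA-256(shared secret ‖ writer pub ‖ reader pub)); recipients find
  their packet by trial decryption, ignoring packets whose tag fails —
  that failure *is* the "not intended for this reader" signal. No
  verifiable packet at all raises `c4gh_no_verifiable_packet`; a data
  segment that no recovered key authenticates raises `c4gh_segment_auth`
  — two deliberately distinct conditions. Plaintext is cut into
  65,536-byte segments, each independently sealed, so
  `c4ghDecryptRange(P, Q)` (0-based half-open internally; the CLI takes
  1-based inclusive coordinates and converts) authenticates and decrypts
  only the overlapping segments. The envelope reuses the package AEAD
  for segments instead of ChaCha20-Poly1305 and is therefore *not*
  bit-compatible with reference Crypt4GH files; the header-packet trial
  decryption, segmenting and range semantics follow the published design.
  Edit lists and recipient re-addition are not implemented.

# Synthetic fixtures and what the tests show

`generateFixture()` builds fully synthetic containers: seeded random block
payloads, EGA-style study metadata, and policies from templates
(`all-permit`, `all-deny`, the worked-example rule at dataset level, or
none). Defaults are desk-scale — 2 groups × 2 datasets × 1 access unit ×
1 block of 1024 bytes — mirroring the granularity of a small multi-sample
study while keeping every test's input a few kilobytes; identical seeds
give byte-identical `packContainer()` output, so fixtures need never be
shipped as files.

The generator emulates the *structure* of archived studies, not their
content: payloads are uniform random bytes, not coded reads, and metadata
values are synthetic strings. Passing tests therefore demonstrate the
container, rule and cryptographic machinery — round-trip identities,
decision correctness against brute-force oracles, AEAD rejection of every
tampering attempt — but say nothing about compression behaviour, real
metadata vocabularies, or performance at hundred-gigabyte scale.

Problem sizes used by the test and acceptance suites, chosen to exercise
every boundary while staying desk-scale: 100 random trees up to 3×3×3×4
nodes with blocks up to 64 KiB for the pack/unpack identity; envelope
payloads from 0 bytes to 1 MiB (1 MiB = 16 segments) with 200 random
byte-ranges checked against the full-decrypt slice; 100 single-byte
corruption trials for tamper detection; exhaustive 4×4 truth tables plus
100 randomized policy configurations against set-builder oracles for the
hierarchy; ±5-position windows around each region boundary and bisection
over 1..10000 for the rule-constant recovery.

# Numerical and degenerate-input choices

Empty payloads are legal everywhere (a zero-length block encrypts and
signs fine; an empty plaintext yields a valid envelope with zero
segments). Box payload lengths are 8-byte integers carried in R doubles,
exact up to 2^53 bytes. Block ids are assigned contiguously from 0 in
append order; children serialize in ascending id order with no
tie-breaking needed since ids are unique by construction. Truncated
streams, unknown box types, malformed XML and out-of-subset XACML all
fail with specific errors rather than best-effort parses; unknown
*metadata* elements, by contrast, are folded into extension attributes,
honoring the metadata model's extension spirit. The NCBI `Type` field is
copied verbatim with no vocabulary translation, as the two type
vocabularies differ and no published correspondence table exists.

# Known limitations

The in-memory metadata index replaces a relational database and rebuilds
on demand; there is no persistence layer, no federation, no Beacon-style
discovery interface. Authentication (tokens, passports) is out of scope:
the request-attribute interface is the trust boundary, and the CLI takes
subject attributes as flags. Access-unit-level rules, DSC organization,
fingerprinting/watermarking, and bit-exact conformance with either the
MPEG-G transport format or reference Crypt4GH files are explicitly not
goals.
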