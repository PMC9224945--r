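Package: GenomicVault
Title: Protected Hierarchical Genomic Containers with Privacy Rules and
    Envelope Encryption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for storing genomic payloads in a hierarchical,
    MPEG-G-style container (dataset groups, datasets, access units and
    blocks) mirrored on the file system, with selective authenticated
    encryption and digital signing of individual payloads, XACML-subset
    privacy rules evaluated by a policy decision engine, hierarchical
    authorization that lets datasets inherit or override dataset-group
    rules, a Crypt4GH-style encrypted-file envelope with per-recipient
    header packets and byte-range decryption, EGA and NCBI study-metadata
    mapping with an attribute-extension mechanism, and authorization-aware
    metadata search.  All protection records are serialized as XML inside
    the container; a command-line interface exposes the container,
    protection and envelope operations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    openssl,
    xml2,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'aead.R'
    'boxio.R'
    'policy.R'
    'policy-xml.R'
    'container.R'
    'protection.R'
    'metadata.R'
    'fixtures.R'
    'hierarchy.R'
    'search.R'
    'crypt4gh.R'
    'cli.R'
    'pack.R'
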