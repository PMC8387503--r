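# Default extended dietary fatty acid subset (C:DnX shorthand), one per line.
# Edit or replace this file to use a lab-specific list.
14:1n5
16:1n11
16:1n9
16:1n7
16:2n6
16:2n4
16:3n6
16:4n3
16:4n1
18:1n11
18:1n9
18:1n7
18:2n6
18:2n4
18:3n6
18:3n4
18:3n3
18:3n1
18:4n3
18:4n1
20:1n11
20:1n9
20:1n7
20:2n6
20:3n6
20:4n6
20:3n3
20:4n3
20:5n3
21:5n3
22:1n11
22:1n9
22:1n7
22:4n6
22:5n6
22:4n3
22:5n3
22:6n3
24:1n9
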