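# Synthetic reconstruction of the worked-example network (13 nodes, 18 edges).
# Built so that every published quantity of node 1's neighborhood recomputes
# exactly; see ?worked_example_graph and ?validate_worked_example.
1 2
1 6
1 7
1 8
2 3
2 4
2 5
2 6
3 4
3 5
3 13
4 5
6 9
7 10
8 10
8 11
9 10
11 12
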