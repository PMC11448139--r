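name	start	end	transfers
pICEoriT	1	463	yes
del4	261	463	yes
del8	298	463	no
del6	1	393	yes
del7	1	349	yes
del9	1	320	yes
del17	1	310	no
del25	261	318	yes
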