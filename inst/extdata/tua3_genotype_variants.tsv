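genotype	gene	variant
U1	TuA3-385	TuA3-385a
U1	TuA3-391	TuA3-373
U1	TuA3-397	TuA3-397a
U1	TuA3-502	TuA3-502c
U1	TuA3-576	TuA3-576d
U1	TuA3-538	TuA3-538a
U2	TuA3-385	TuA3-385b
U2	TuA3-391	TuA3-391
U2	TuA3-397	TuA3-397a
U2	TuA3-502	TuA3-502b
U2	TuA3-576	TuA3-406
U2	TuA3-538	TuA3-538c
U3	TuA3-385	TuA3-385a
U3	TuA3-391	TuA3-391
U3	TuA3-397	TuA3-397a
U3	TuA3-502	TuA3-498
U3	TuA3-576	TuA3-597
U3	TuA3-538	TuA3-535
U4	TuA3-385	TuA3-385b
U4	TuA3-391	TuA3-392
U4	TuA3-397	TuA3-397a
U4	TuA3-502	TuA3-520
U4	TuA3-576	TuA3-576c
U4	TuA3-538	TuA3-538d
U5	TuA3-385	TuA3-385a
U5	TuA3-391	TuA3-392
U5	TuA3-397	TuA3-397a
U5	TuA3-502	TuA3-502c
U5	TuA3-576	TuA3-576b
U5	TuA3-538	TuA3-538b
U6	TuA3-385	TuA3-385a
U6	TuA3-391	TuA3-392
U6	TuA3-397	TuA3-397a
U6	TuA3-502	TuA3-502a
U6	TuA3-576	TuA3-576a
U6	TuA3-538	TuA3-538a
U7	TuA3-385	TuA3-385a
U7	TuA3-391	TuA3-392
U7	TuA3-397	TuA3-397a
U7	TuA3-502	TuA3-502d
U7	TuA3-576	TuA3-555
U7	TuA3-538	TuA3-538a
U8	TuA3-385	TuA3-385a
U8	TuA3-391	TuA3-392
U8	TuA3-397	TuA3-397b
U8	TuA3-502	TuA3-502a
U8	TuA3-576	TuA3-579b
U8	TuA3-538	TuA3-538b
U9	TuA3-385	TuA3-385a
U9	TuA3-391	TuA3-392
U9	TuA3-397	TuA3-397a
U9	TuA3-502	TuA3-593
U9	TuA3-576	TuA3-576b
U9	TuA3-538	TuA3-538e
U10	TuA3-385	TuA3-385a
U10	TuA3-391	TuA3-373
U10	TuA3-397	TuA3-397a
U10	TuA3-460	TuA3-460
U10	TuA3-502	TuA3-502a
U10	TuA3-576	TuA3-579a
U10	TuA3-538	TuA3-538b
U11	TuA3-385	TuA3-385a
U11	TuA3-391	TuA3-373
U11	TuA3-397	TuA3-397a
U11	TuA3-460	TuA3-463
U11	TuA3-502	TuA3-520
U11	TuA3-576	TuA3-576c
U11	TuA3-538	TuA3-538a
U12	TuA3-385	TuA3-385b
U12	TuA3-391	TuA3-373
U12	TuA3-397	TuA3-397a
U12	TuA3-460	TuA3-463
U12	TuA3-502	TuA3-495
U12	TuA3-576	TuA3-669
U12	TuA3-538	TuA3-657
U13	TuA3-385	TuA3-385a
U13	TuA3-391	TuA3-392
U13	TuA3-397	TuA3-397a
U13	TuA3-460	TuA3-474
U13	TuA3-502	TuA3-502c
U13	TuA3-576	TuA3-576d
U13	TuA3-538	TuA3-538d
U14	TuA3-385	TuA3-385a
U14	TuA3-391	TuA3-392
U14	TuA3-397	TuA3-397a
U14	TuA3-400	TuA3-402
U14	TuA3-502	TuA3-520
U14	TuA3-576	TuA3-576c
U14	TuA3-538	TuA3-538a
U15	TuA3-391	TuA3-392
U15	TuA3-397	TuA3-397b
U15	TuA3-400	TuA3-400
U15	TuA3-502	TuA3-590
U15	TuA3-576	TuA3-576e
U15	TuA3-538	TuA3-538a
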