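cluster	wave	policy_start	policy_end	heat_start	heat_end
children_pregnant_patients	1	2020-01-28	2020-04-09	2020-01-28	2020-02-07
children_pregnant_patients	2	2020-05-08	2020-06-01	2020-02-27	2020-03-28
aged_patients	1	2020-01-29	2020-02-26	2020-01-28	2020-02-07
aged_patients	2	2020-04-08	2020-05-29	2020-02-17	2020-06-26
severe_symptoms	1	2020-01-28	2020-04-11	2020-02-07	2020-03-08
severe_symptoms	2	2020-05-08	2020-06-08	2020-05-17	2020-06-16
asymptomatic_infection	1	2020-02-04	2020-02-21	2020-02-07	2020-02-27
asymptomatic_infection	2	2020-04-08	2020-06-08	2020-03-18	2020-03-28
antibody_test	1	2020-04-05	2020-05-08	2020-04-08	2020-05-27
chinese_medicine	1	2020-01-26	2020-03-04	2020-02-07	2020-03-08
chinese_medicine	2	2020-05-14	2020-05-22
mental_health	1	2020-01-27	2020-05-08	2020-02-17	2020-02-27
mental_health	2			2020-03-18	2020-04-27
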