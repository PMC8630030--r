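id	branch	parent	author	message	timestamp
1	main	NA	ana	initial protocol import	1000
2	main	1	ben	tune packer weights	1010
3	main	2	ana	fix loop closure edge case	1020
4	main	3	cyd	refactor scoring pipeline	1030
5	main	4	ben	update default score function	1040
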