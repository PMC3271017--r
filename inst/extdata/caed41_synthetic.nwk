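((((((t32:0.2156540116,t39:0.07205062289)n6:0.1331952262,(((t10:0.5760499254,t29:0.4804741155)n9:0.2278975353,t35:0.5296608809)n8:0.1744760549,(t16:0.4153925937,t36:0.1911816161)n10:0.03718730034)n7:0.2306804921)n5:0.2124572232,((t33:0.09086649353,t26:0.2323184894)n12:0.3464440979,t27:0.05385790591)n11:0.1964924952)n4:0.05320177777,((t20:0.04446516568,t7:0.05810276504)n14:0.06464912156,(t28:0.3336667534,(t30:0.2380454019,t15:0.04977849789)n16:0.09300752236)n15:0.1972694062)n13:0.04960214775)n3:0.2279603934,(((((t24:0.01304547908,(t17:0.1593959059,t3:0.06155894014)n22:0.003151128304)n21:0.0950950291,(t4:0.01159853498,t34:0.306319444)n23:0.09328896794)n20:0.02503446992,((((t22:0.006552271638,t23:0.2929383505)n27:0.449621072,t21:0.103359777)n26:0.1878532775,((t41:0.8832269109,t31:0.06523272973)n29:0.4588102888,t13:0.05448349314)n28:0.920158068)n25:0.4792872492,((t6:0.1639122651,t14:0.09361912133)n31:0.03822169499,(t38:0.8114580284,t12:0.4116324968)n32:0.003632449433)n30:0.003184092883)n24:0.1782694492)n19:0.08132046962,(t25:0.009933636617,(t40:0.1159105167,(t1:0.06423831489,t11:0.03260735432)n35:0.0637552131)n34:0.05563270365)n33:0.3435122438)n18:0.5191334087,((t18:0.1911846842,t19:0.2910903104)n37:0.1454114657,(t8:0.2740592606,(t2:0.1865885515,t37:0.1245817734)n39:0.608090879)n38:0.4528383139)n36:0.02566060992)n17:0.5519157383)n2:0.4255459747,(t5:0.5154628556,t9:0.1109902263)n40:0.261777965)n1;
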